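# Causal estimators on the log-odds-ratio-per-SD scale: per-variant Wald
# ratios and the three pooled methods (IVW with multiplicative random
# effects, weighted median, MR-Egger). All interval estimates use normal
# quantiles; 95% intervals use z = 1.959964 throughout.

new_mr_estimate <- function(method, n_variants, theta_hat, se, inflation = 1) {
  stopifnot(se > 0, inflation >= 1)
  ci_low <- theta_hat - Z95 * se
  ci_high <- theta_hat + Z95 * se
  structure(list(method = method,
                 n_variants = as.integer(n_variants),
                 theta_hat = theta_hat,
                 se = se,
                 ci_low = ci_low,
                 ci_high = ci_high,
                 p = 2 * stats::pnorm(-abs(theta_hat / se)),
                 inflation = inflation,
                 or_point = exp(theta_hat),
                 or_low = exp(ci_low),
                 or_high = exp(ci_high)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d variants): OR %.3g (95%% CI %.3g, %.3g), p = %.3g\n",
              x$method, x$n_variants, x$or_point, x$or_low, x$or_high, x$p))
  if (x$inflation > 1) {
    cat(sprintf("  multiplicative SE inflation: %.3f\n", x$inflation))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_variants = x$n_variants,
             theta = x$theta_hat, se = x$se, or = x$or_point,
             ci_low = x$or_low, ci_high = x$or_high, p = x$p,
             inflation = x$inflation, stringsAsFactors = FALSE)
}

#' Per-variant Wald ratio estimates
#'
#' The Wald ratio for variant j is `theta_j = gamma_j / beta_j`: the outcome
#' log-odds change per SD of the exposure implied by that variant alone. The
#' default first-order standard error `se(gamma_j)/|beta_j|` ignores the
#' uncertainty in the exposure beta, so the ratio's z and p equal those of
#' the variant-outcome association; `order = "second"` adds the exposure-beta
#' term `sqrt(se_g^2/b^2 + g^2 se_b^2/b^4)`.
#'
#' @param set A [harmonized_set()] (any number of variants).
#' @param order `"first"` (default) or `"second"` order delta-method SE.
#' @return A data frame of class `ratio_estimates` with columns `variant_id`,
#'   `theta`, `se`, `z`, `p` and `weight` (`1/se^2`).
#' @export
wald_ratio <- function(set, order = c("first", "second")) {
  order <- match.arg(order)
  stopifnot(inherits(set, "harmonized_set"))
  if (any(set$beta_exposure == 0)) {
    stop("zero exposure beta for variant ",
         paste(set$variant_id[set$beta_exposure == 0], collapse = ", "),
         call. = FALSE)
  }
  b <- set$beta_exposure
  g <- set$beta_outcome
  theta <- g / b
  se <- if (order == "first") {
    set$se_outcome / abs(b)
  } else {
    sqrt(set$se_outcome^2 / b^2 + g^2 * set$se_exposure^2 / b^4)
  }
  z <- theta / se
  structure(data.frame(variant_id = set$variant_id,
                       theta = theta, se = se, z = z,
                       p = 2 * stats::pnorm(-abs(z)),
                       weight = 1 / se^2,
                       stringsAsFactors = FALSE),
            exposure_id = attr(set, "exposure_id"),
            outcome_id = attr(set, "outcome_id"),
            class = c("ratio_estimates", "data.frame"))
}

as_ratio_estimates <- function(ratios) {
  stopifnot(is.data.frame(ratios),
            all(c("theta", "se") %in% names(ratios)))
  if (any(ratios$se <= 0)) stop("ratio SEs must be > 0", call. = FALSE)
  ratios$weight <- 1 / ratios$se^2
  ratios
}

#' Inverse-variance-weighted pooled causal estimate
#'
#' Pools per-variant Wald ratios with weights `w_j = 1/se_j^2`:
#' `theta_hat = sum(w theta) / sum(w)` with fixed-effect standard error
#' `1/sqrt(sum(w))`. Under the multiplicative random-effects model the
#' standard error is inflated by `phi = max(1, sqrt(Q/(L-1)))`, where Q is
#' Cochran's heterogeneity statistic, leaving the point estimate unchanged.
#'
#' @param ratios A `ratio_estimates` data frame (from [wald_ratio()]), or any
#'   data frame with `theta` and `se` columns.
#' @param effects `"random"` (default, as used for the iron-cancer analyses)
#'   or `"fixed"`.
#' @return An `mr_estimate` object.
#' @export
mr_ivw <- function(ratios, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  ratios <- as_ratio_estimates(ratios)
  L <- nrow(ratios)
  if (L == 0L) stop("no ratio estimates supplied", call. = FALSE)
  w <- ratios$weight
  theta_hat <- sum(w * ratios$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  phi <- 1
  method <- paste0("ivw-", effects)
  if (effects == "random") {
    if (L < 2L) {
      warning("single variant: returning fixed-effect estimate", call. = FALSE)
      method <- "ivw-fixed"
    } else {
      q <- cochran_q(ratios)
      phi <- max(1, sqrt(q$q / q$df))
    }
  }
  new_mr_estimate(method, L, theta_hat, phi * se_fixed, inflation = phi)
}

# Point estimate of the weighted median: linear interpolation of the
# weighted empirical CDF of sorted ratios at probability 0.5, evaluated at
# the cumulative weight midpoints s_j = sum_{k<j} p_k + p_j / 2.
weighted_median_point <- function(theta, weight) {
  ord <- order(theta)
  theta <- theta[ord]
  p <- weight[ord] / sum(weight)
  s <- cumsum(p) - p / 2
  if (s[1] > 0.5) return(theta[1])
  if (s[length(s)] < 0.5) return(theta[length(s)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The median of the inverse-variance-weighted empirical distribution of the
#' Wald ratios: consistent when valid instruments carry more than half of
#' the total weight. The standard error comes from a parametric bootstrap
#' (each ratio resampled from `Normal(theta_j, se_j)`, the weighted median
#' recomputed `n_boot` times); the point estimate does not depend on the
#' bootstrap. The global RNG state is left untouched.
#'
#' @param ratios A `ratio_estimates` data frame with at least 3 rows.
#' @param n_boot Number of bootstrap replicates; default 10000.
#' @param seed Integer seed for the bootstrap (mandatory, for
#'   reproducibility).
#' @param ci `"normal"` (default): `theta_hat +/- 1.96 * se(boot)`;
#'   `"quantile"`: the 2.5% and 97.5% bootstrap quantiles (the p-value is
#'   still normal-based).
#' @return An `mr_estimate` object.
#' @export
mr_weighted_median <- function(ratios, n_boot = 10000L, seed,
                               ci = c("normal", "quantile")) {
  ci <- match.arg(ci)
  ratios <- as_ratio_estimates(ratios)
  if (nrow(ratios) < 3L) {
    stop("weighted median needs at least 3 variants", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_boot >= 1L)
  theta_hat <- weighted_median_point(ratios$theta, ratios$weight)
  L <- nrow(ratios)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      th <- stats::rnorm(L, ratios$theta, ratios$se)
      weighted_median_point(th, ratios$weight)
    }, numeric(1))
  })
  est <- new_mr_estimate("weighted-median", L, theta_hat, stats::sd(boots))
  if (ci == "quantile") {
    qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    est$ci_low <- qs[1]
    est$ci_high <- qs[2]
    est$or_low <- exp(qs[1])
    est$or_high <- exp(qs[2])
  }
  est
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome effects `gamma_j` on the
#' exposure effects `beta_j` with a free intercept, weights
#' `1/se(gamma_j)^2`, after orienting every pair so the exposure effect is
#' positive. The slope estimates the causal effect under the InSIDE
#' assumption; a nonzero intercept indicates directional pleiotropy.
#' Standard errors are the weighted-regression SEs at unit dispersion,
#' inflated by `max(1, sqrt(Q_residual/(L-2)))`; inference uses normal
#' quantiles.
#'
#' @param set A [harmonized_set()] with at least 3 variants.
#' @return An object of class `egger_fit`: a list with `slope` (an
#'   `mr_estimate`), `intercept`, `se_intercept`, `ci_low_intercept`,
#'   `ci_high_intercept`, `p_intercept`, `residual_q` and `inflation`.
#' @export
mr_egger <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  L <- nrow(set)
  if (L < 3L) stop("MR-Egger needs at least 3 variants", call. = FALSE)
  flip <- sign(set$beta_exposure)
  b <- set$beta_exposure * flip
  g <- set$beta_outcome * flip
  w <- 1 / set$se_outcome^2
  sw <- sum(w)
  xbar <- sum(w * b) / sw
  ybar <- sum(w * g) / sw
  sxx <- sum(w * (b - xbar)^2)
  if (sxx <= 0) stop("degenerate exposure betas", call. = FALSE)
  slope <- sum(w * (b - xbar) * (g - ybar)) / sxx
  intercept <- ybar - slope * xbar
  residual_q <- sum(w * (g - intercept - slope * b)^2)
  phi <- max(1, sqrt(residual_q / (L - 2)))
  se_slope <- phi / sqrt(sxx)
  se_intercept <- phi * sqrt(1 / sw + xbar^2 / sxx)
  structure(list(
    slope = new_mr_estimate("mr-egger-slope", L, slope, se_slope,
                            inflation = phi),
    intercept = intercept,
    se_intercept = se_intercept,
    ci_low_intercept = intercept - Z95 * se_intercept,
    ci_high_intercept = intercept + Z95 * se_intercept,
    p_intercept = 2 * stats::pnorm(-abs(intercept / se_intercept)),
    residual_q = residual_q,
    inflation = phi), class = "egger_fit")
}

#' @export
print.egger_fit <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
              x$intercept, x$ci_low_intercept, x$ci_high_intercept,
              x$p_intercept))
  invisible(x)
}
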