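# Heterogeneity and pleiotropy diagnostics plus the sensitivity analyses:
# per-variant tables, leave-one-out, and explicit variant exclusion.

#' Cochran's Q and the I-squared heterogeneity statistic
#'
#' Q is the weighted squared deviation of the per-variant ratios around the
#' fixed-effect pooled estimate, `sum(w_j (theta_j - theta_fixed)^2)`,
#' referred to a chi-square with `L - 1` df. `I2 = max(0, (Q - df)/Q) * 100`
#' expresses the share of variation beyond sampling noise. The I-squared CI
#' is the test-based interval on `ln H` (`H = max(1, sqrt(Q/df))`), with the
#' usual two-case standard error (one form for Q > L, another for Q <= L),
#' truncated to `[0, 100]`.
#'
#' @param ratios A `ratio_estimates` data frame with at least 2 rows.
#' @return A list of class `het_stats`: `q`, `df`, `p`, `i2`, `i2_low`,
#'   `i2_high`.
#' @export
cochran_q <- function(ratios) {
  ratios <- as_ratio_estimates(ratios)
  L <- nrow(ratios)
  if (L < 2L) stop("heterogeneity needs at least 2 variants", call. = FALSE)
  w <- ratios$weight
  theta_fixed <- sum(w * ratios$theta) / sum(w)
  q <- sum(w * (ratios$theta - theta_fixed)^2)
  df <- L - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  # test-based CI on ln H (Higgins-Thompson)
  ln_h <- log(max(1, sqrt(q / df)))
  se_ln_h <- if (q > L) {
    0.5 * (log(q) - log(df)) / (sqrt(2 * q) - sqrt(2 * L - 3))
  } else if (L > 2) {
    sqrt(1 / (2 * (L - 2)) * (1 - 1 / (3 * (L - 2)^2)))
  } else {
    Inf  # two estimates: the interval is vacuous, (0, 100)
  }
  h_to_i2 <- function(h) max(0, min(100, 100 * (h^2 - 1) / h^2))
  structure(list(q = q, df = df,
                 p = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = i2,
                 i2_low = h_to_i2(exp(ln_h - Z95 * se_ln_h)),
                 i2_high = h_to_i2(exp(ln_h + Z95 * se_ln_h))),
            class = "het_stats")
}

#' @export
print.het_stats <- function(x, ...) {
  cat(sprintf("Q = %.3f on %d df (p = %.3g); I2 = %.0f%% (95%% CI %.0f, %.0f)\n",
              x$q, x$df, x$p, x$i2, x$i2_low, x$i2_high))
  invisible(x)
}

#' Directional-pleiotropy test from an MR-Egger fit
#'
#' Repackages the intercept of an [mr_egger()] fit as a labelled test record:
#' under no directional pleiotropy the intercept is zero, and the two-sided
#' normal p-value tests that null.
#'
#' @param fit An `egger_fit` from [mr_egger()].
#' @return A data frame row with `intercept`, `se`, `ci_low`, `ci_high`, `p`.
#' @export
egger_intercept_test <- function(fit) {
  stopifnot(inherits(fit, "egger_fit"))
  data.frame(intercept = fit$intercept, se = fit$se_intercept,
             ci_low = fit$ci_low_intercept, ci_high = fit$ci_high_intercept,
             p = fit$p_intercept)
}

#' Per-variant causal estimate table
#'
#' One Wald ratio per variant in input order — the per-SNP block of a
#' sensitivity table.
#'
#' @param set A [harmonized_set()].
#' @param order Delta-method order passed to [wald_ratio()].
#' @return A `ratio_estimates` data frame.
#' @export
single_variant_table <- function(set, order = "first") {
  wald_ratio(set, order = order)
}

fit_method <- function(set, method, n_boot = 10000L, seed = NULL) {
  ratios <- wald_ratio(set)
  switch(method,
         "ivw-random" = mr_ivw(ratios, effects = "random"),
         "ivw-fixed" = mr_ivw(ratios, effects = "fixed"),
         "weighted-median" = {
           if (is.null(seed)) stop("`seed` required for weighted-median",
                                   call. = FALSE)
           mr_weighted_median(ratios, n_boot = n_boot, seed = seed)
         },
         "mr-egger" = mr_egger(set),
         stop("unknown method: ", method, call. = FALSE))
}

method_feasible <- function(method, L) {
  switch(method,
         "ivw-random" = L >= 1L,
         "ivw-fixed" = L >= 1L,
         "weighted-median" = L >= 3L,
         "mr-egger" = L >= 3L,
         FALSE)
}

#' Leave-one-out and exclusion sensitivity analysis
#'
#' Re-fits the chosen estimator once per variant with that variant removed,
#' and once with an explicit exclusion list removed (by default rs1800562,
#' the *HFE* variant that dominates the iron instruments). Entries where the
#' estimator is infeasible on the reduced set (for example the weighted
#' median on fewer than 3 variants) are marked `NULL` rather than failing.
#'
#' @param set A [harmonized_set()] with at least 2 variants.
#' @param method One of `"ivw-random"`, `"ivw-fixed"`, `"weighted-median"`,
#'   `"mr-egger"`.
#' @param exclude Character vector of variant ids for the exclusion re-run;
#'   `character(0)` skips it.
#' @param n_boot,seed Bootstrap settings forwarded to the weighted median.
#' @return A list of class `sensitivity_report`: `per_variant` (Wald-ratio
#'   table), `leave_one_out` (named list of `mr_estimate` or `NULL` when
#'   infeasible), `excluded_rerun` (an `mr_estimate`, `NULL` when infeasible
#'   or no exclusions requested) and `excluded` (the ids actually removed).
#' @export
leave_one_out <- function(set, method = "ivw-random",
                          exclude = "rs1800562",
                          n_boot = 10000L, seed = NULL) {
  stopifnot(inherits(set, "harmonized_set"))
  L <- nrow(set)
  if (L < 2L) stop("leave-one-out needs at least 2 variants", call. = FALSE)
  subset_set <- function(keep) {
    harmonized_set(as.data.frame(set)[keep, , drop = FALSE],
                   exposure_id = attr(set, "exposure_id"),
                   outcome_id = attr(set, "outcome_id"),
                   label = attr(set, "label"))
  }
  fit_or_null <- function(s) {
    if (!method_feasible(method, nrow(s))) return(NULL)
    fit_method(s, method, n_boot = n_boot, seed = seed)
  }
  loo <- lapply(seq_len(L), function(j) fit_or_null(subset_set(-j)))
  names(loo) <- set$variant_id
  excluded <- intersect(exclude, set$variant_id)
  rerun <- NULL
  if (length(excluded) && length(excluded) < L) {
    rerun <- fit_or_null(subset_set(!set$variant_id %in% excluded))
  }
  structure(list(per_variant = single_variant_table(set),
                 leave_one_out = loo,
                 excluded_rerun = rerun,
                 excluded = excluded),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Per-variant Wald ratios:\n")
  print(as.data.frame(x$per_variant))
  cat("\nLeave-one-out estimates:\n")
  for (id in names(x$leave_one_out)) {
    est <- x$leave_one_out[[id]]
    cat("  without ", id, ": ", sep = "")
    if (is.null(est)) cat("infeasible\n") else
      cat(sprintf("OR %.3g (%.3g, %.3g)\n", est$or_point, est$or_low,
                  est$or_high))
  }
  if (!is.null(x$excluded_rerun)) {
    cat("\nExcluding ", paste(x$excluded, collapse = ", "), ": ", sep = "")
    print(x$excluded_rerun)
  }
  invisible(x)
}
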