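# Brute-force oracles, written as plainly as possible and kept independent
# of the estimator code paths they check.

# IVW fixed-effect pooled estimate by explicit accumulation.
ivw_brute <- function(theta, se) {
  num <- 0
  den <- 0
  for (j in seq_along(theta)) {
    w <- 1 / se[j]^2
    num <- num + w * theta[j]
    den <- den + w
  }
  list(theta_hat = num / den, se = 1 / sqrt(den))
}

# Cochran's Q via the pairwise identity Q = sum_{i<j} w_i w_j
# (theta_i - theta_j)^2 / sum(w) — a different formula from the
# deviation-from-the-mean form used in the package.
q_brute <- function(theta, se) {
  w <- 1 / se^2
  total <- 0
  for (i in seq_along(theta)) {
    for (j in seq_along(theta)) {
      if (i < j) total <- total + w[i] * w[j] * (theta[i] - theta[j])^2
    }
  }
  total / sum(w)
}

# Weighted-median point estimate by stepping through the sorted ratios and
# interpolating where the cumulative-weight midpoints cross one half.
weighted_median_brute <- function(theta, weight) {
  ord <- order(theta)
  theta <- theta[ord]
  p <- weight[ord] / sum(weight)
  s <- numeric(length(p))
  acc <- 0
  for (j in seq_along(p)) {
    s[j] <- acc + p[j] / 2
    acc <- acc + p[j]
  }
  if (s[1] > 0.5) return(theta[1])
  if (s[length(s)] < 0.5) return(theta[length(s)])
  for (j in seq_len(length(s) - 1)) {
    if (s[j] <= 0.5 && 0.5 <= s[j + 1]) {
      return(theta[j] + (theta[j + 1] - theta[j]) *
               (0.5 - s[j]) / (s[j + 1] - s[j]))
    }
  }
  stop("unreachable")
}

# Random ratio-estimate sets for property tests.
random_ratios <- function(L, rng_seed) {
  withr::with_seed(rng_seed, {
    data.frame(variant_id = paste0("rs", seq_len(L)),
               theta = stats::rnorm(L, 0, 0.8),
               se = stats::runif(L, 0.05, 0.6))
  })
}

# Small harmonized set with controllable effects.
make_set <- function(beta, se_b, gamma, se_g, ids = NULL,
                     exposure = "x", outcome = "y") {
  ids <- ids %||% paste0("rs", seq_along(beta))
  harmonized_set(data.frame(variant_id = ids, beta_exposure = beta,
                            se_exposure = se_b, beta_outcome = gamma,
                            se_outcome = se_g, stringsAsFactors = FALSE),
                 exposure_id = exposure, outcome_id = outcome)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Agreement within one unit in the last printed significant digit, the
# precision at which the published tables are typeset. `printed_str` is the
# value exactly as typeset (e.g. "0.30", "49.0") so trailing zeros count.
matches_printed <- function(value, printed_str) {
  printed <- as.numeric(printed_str)
  digits <- nchar(sub("^0+", "", gsub("[^0-9]", "", printed_str)))
  ulp <- 10^(floor(log10(abs(printed))) - digits + 1)
  abs(signif(value, digits) - printed) <= ulp * 1.0000001
}
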