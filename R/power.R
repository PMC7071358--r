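# Analytic power for two-sample MR with a binary outcome.

#' Power of a two-sample MR test with a binary outcome
#'
#' Uses the standard large-sample approximation for the standard error of
#' the causal log-odds ratio, `se = 1/sqrt(n * r2 * K * (1 - K))`, where `n`
#' is the outcome-study sample size, `K` the case fraction and `r2` the
#' share of exposure variance explained by the instruments. Power of the
#' two-sided level-`alpha` test of a true odds ratio `or_per_sd` is then
#' `pnorm(|ln OR| / se - z_{1-alpha/2})`.
#'
#' At `or_per_sd = 1` this reduces to `alpha/2` (one tail of the test size),
#' and it is symmetric in `OR` and `1/OR`.
#'
#' @param n Outcome-study sample size (>= 1).
#' @param k Case fraction, strictly in (0, 1). Supply either `k` or `cases`.
#' @param r2 Instrument variance explained, strictly in (0, 1).
#' @param or_per_sd Hypothesized odds ratio per SD of exposure (> 0).
#' @param alpha Two-sided significance level, strictly in (0, 1);
#'   default 0.05.
#' @param cases Optional case count; used as `k = cases/n` when `k` missing.
#' @return Power in (0, 1). Vectorized over its numeric arguments.
#' @export
mr_power_binary <- function(n, k, r2, or_per_sd, alpha = 0.05,
                            cases = NULL) {
  if (missing(k)) {
    if (is.null(cases)) stop("supply `k` or `cases`", call. = FALSE)
    k <- cases / n
  }
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  if (any(k <= 0 | k >= 1)) stop("`k` must lie in (0, 1)", call. = FALSE)
  if (any(r2 <= 0 | r2 >= 1)) stop("`r2` must lie in (0, 1)", call. = FALSE)
  if (any(or_per_sd <= 0)) stop("`or_per_sd` must be > 0", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  se_approx <- 1 / sqrt(n * r2 * k * (1 - k))
  stats::pnorm(abs(log(or_per_sd)) / se_approx -
                 stats::qnorm(1 - alpha / 2))
}
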