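# Seeded generator of two-sample GWAS summary statistics with known causal
# truth, emulating the structure of the iron-cancer design: SD-unit exposure
# betas estimated in a moderately sized GWAS, binary-outcome log-odds ratios
# from a large cohort with a small case fraction.

#' Simulation configuration for two-sample summary statistics
#'
#' @param n_variants Number of instruments L (>= 1).
#' @param n_exposure Exposure GWAS sample size.
#' @param n_outcome Outcome GWAS sample size.
#' @param case_fraction Outcome case fraction K, strictly in (0, 1).
#' @param total_r2 Exposure variance jointly explained by the instruments,
#'   strictly in (0, 1).
#' @param theta True causal log-odds ratio per SD of exposure.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-variant direct
#'   (pleiotropic) effects alpha_j on the outcome; both 0 for valid
#'   instruments.
#' @param inside_violation If `TRUE`, the pleiotropic effects are made
#'   rank-correlated with instrument strength `|beta_j|` (Spearman about
#'   0.9), violating the InSIDE assumption that MR-Egger relies on.
#' @param eaf_range Interval inside (0, 1) from which effect-allele
#'   frequencies are drawn uniformly.
#' @param seed Integer seed (mandatory): identical configurations give
#'   bit-identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 3L, n_exposure = 48972L,
                       n_outcome = 367643L, case_fraction = 0.01,
                       total_r2 = 0.034, theta = 0,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       inside_violation = FALSE,
                       eaf_range = c(0.05, 0.95), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_variants >= 1L, n_exposure >= 1, n_outcome >= 1,
            pleiotropy_sd >= 0, length(eaf_range) == 2L)
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("`case_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (total_r2 <= 0 || total_r2 >= 1) {
    stop("`total_r2` must lie in (0, 1)", call. = FALSE)
  }
  if (eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] >= eaf_range[2]) {
    stop("`eaf_range` must be an interval inside (0, 1)", call. = FALSE)
  }
  structure(list(n_variants = as.integer(n_variants),
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 case_fraction = case_fraction, total_r2 = total_r2,
                 theta = theta, pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 inside_violation = isTRUE(inside_violation),
                 eaf_range = eaf_range, seed = as.integer(seed)),
            class = "sim_config")
}

# Two-sided normal p floored at the smallest positive double so extreme
# z-scores at large sample sizes do not underflow the (0, 1] invariant.
sim_p <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

# Reorder `alpha` so its ranks track rank(|beta|) with Spearman ~ 0.9,
# preserving the marginal distribution of alpha.
rank_correlate <- function(alpha, beta) {
  L <- length(alpha)
  if (L < 2L) return(alpha)
  target <- rank(abs(beta)) + stats::rnorm(L, sd = 0.2 * L)
  sort(alpha)[rank(target, ties.method = "first")]
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates, under the given seed: uniform effect-allele frequencies; true
#' per-variant exposure effects `beta_j` (standard-normal draws rescaled so
#' the total explained variance `sum(2 p_j (1-p_j) beta_j^2)` equals
#' `total_r2`); observed exposure estimates `Normal(beta_j, se_bj)` with
#' `se_bj = [2 p_j (1-p_j) n_exposure]^{-1/2}`; pleiotropic effects
#' `alpha_j ~ Normal(mu, sigma)` (rank-reordered against `|beta_j|` when
#' `inside_violation`); true outcome effects `gamma_j = theta beta_j +
#' sign(beta_j) alpha_j` — the pleiotropic effect acts in the
#' exposure-increasing-allele frame, so a positive `pleiotropy_mean` means
#' directional pleiotropy — and observed estimates `Normal(gamma_j, se_gj)`
#' with
#' `se_gj = [2 p_j (1-p_j) n_outcome K (1-K)]^{-1/2}`. Variants are
#' simulated unlinked, matching the mutual independence of the iron
#' instruments.
#'
#' All variants are written with effect allele A / other allele G so the
#' two tables harmonize without flips.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `config`, `true_beta`,
#'   `true_alpha`, `exposure` and `outcome` (both [instrument_table()]s),
#'   and `harmonized` (the aligned [harmonized_set()]).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  c_ <- config
  L <- c_$n_variants
  withr::with_seed(c_$seed, {
    eaf <- stats::runif(L, c_$eaf_range[1], c_$eaf_range[2])
    het <- 2 * eaf * (1 - eaf)
    beta_raw <- stats::rnorm(L)
    scale <- sqrt(c_$total_r2 / sum(het * beta_raw^2))
    beta <- beta_raw * scale
    alpha <- stats::rnorm(L, c_$pleiotropy_mean, c_$pleiotropy_sd)
    if (c_$inside_violation) alpha <- rank_correlate(alpha, beta)
    se_b <- 1 / sqrt(het * c_$n_exposure)
    beta_hat <- stats::rnorm(L, beta, se_b)
    # directional pleiotropy is defined relative to the exposure-increasing
    # allele: a positive mean direct effect must survive re-orientation, so
    # alpha enters with the sign of the exposure beta
    gamma <- c_$theta * beta + sign(beta) * alpha
    se_g <- 1 / sqrt(het * c_$n_outcome *
                       c_$case_fraction * (1 - c_$case_fraction))
    gamma_hat <- stats::rnorm(L, gamma, se_g)
  })
  ids <- sprintf("sim%0*d", nchar(L), seq_len(L))
  exposure <- instrument_table(
    data.frame(variant_id = ids, effect_allele = "A", other_allele = "G",
               eaf = eaf, beta = beta_hat, se = se_b,
               pvalue = sim_p(beta_hat / se_b),
               n = c_$n_exposure, stringsAsFactors = FALSE),
    trait_id = "sim_exposure", variance_explained = c_$total_r2)
  outcome <- instrument_table(
    data.frame(variant_id = ids, effect_allele = "A", other_allele = "G",
               eaf = eaf, beta = gamma_hat, se = se_g,
               pvalue = sim_p(gamma_hat / se_g),
               n = c_$n_outcome, stringsAsFactors = FALSE),
    trait_id = "sim_outcome")
  harmonized <- harmonized_set(
    data.frame(variant_id = ids, beta_exposure = beta_hat,
               se_exposure = se_b, beta_outcome = gamma_hat,
               se_outcome = se_g, stringsAsFactors = FALSE),
    exposure_id = "sim_exposure", outcome_id = "sim_outcome",
    label = "simulated")
  structure(list(config = c_, true_beta = beta, true_alpha = alpha,
                 exposure = exposure, outcome = outcome,
                 harmonized = harmonized),
            class = "sim_dataset")
}

# UK Biobank case counts for the cancer sites with bundled fixtures.
.site_cases <- c(liver = 324, brain = 810, overall = 75037)

#' Simulation scenario at the scale of the iron-cancer study
#'
#' Returns a [sim_config()] matching the real design: exposure GWAS of
#' 48,972, outcome cohort of 367,643 with the observed case count for the
#' chosen cancer site, three instruments, and the serum-iron variance
#' explained (3.4%) by default.
#'
#' @param site `"liver"` (324 cases), `"brain"` (810) or `"overall"`
#'   (75,037).
#' @param theta True causal log-odds ratio per SD; default 0.
#' @param total_r2 Instrument variance explained; default 0.034.
#' @param seed Integer seed (mandatory).
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
cohort_scenario <- function(site = c("liver", "brain", "overall"),
                            theta = 0, total_r2 = 0.034, seed, ...) {
  site <- match.arg(site)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_outcome <- 367643
  sim_config(n_variants = 3L, n_exposure = 48972L, n_outcome = n_outcome,
             case_fraction = .site_cases[[site]] / n_outcome,
             total_r2 = total_r2, theta = theta, seed = seed, ...)
}
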