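#!/usr/bin/env Rscript
# Step 3: calibration of the estimator suite on synthetic two-sample
# summary statistics with known causal truth, at two scales:
#   (a) idealized large samples (L = 30, n = 1e6 per study) to check
#       bias, pleiotropy recovery and robustness of the weighted median;
#   (b) the liver-cancer scale (324 cases among 367,643) to show how wide
#       the realistic sampling distribution is.
#
# Output: results/simulation_calibration.tsv

library(ironmr)

dir.create("results", showWarnings = FALSE)

big <- function(seed, theta, mu = 0, sdev = 0, inside = FALSE) {
  sim_config(n_variants = 30L, n_exposure = 1e6, n_outcome = 1e6,
             case_fraction = 0.1, total_r2 = 0.1, theta = theta,
             pleiotropy_mean = mu, pleiotropy_sd = sdev,
             inside_violation = inside, seed = seed)
}

run_scenario <- function(label, cfg_fun, n_rep) {
  ests <- t(vapply(seq_len(n_rep), function(s) {
    d <- simulate_two_sample(cfg_fun(s))
    r <- wald_ratio(d$harmonized)
    fit <- mr_egger(d$harmonized)
    c(ivw = mr_ivw(r, effects = "fixed")$theta_hat,
      wm = mr_weighted_median(r, n_boot = 2, seed = 1)$theta_hat,
      egger_slope = fit$slope$theta_hat,
      egger_intercept = fit$intercept)
  }, numeric(4)))
  data.frame(scenario = label, estimator = colnames(ests),
             mean = colMeans(ests), sd = apply(ests, 2, sd),
             n_rep = n_rep, row.names = NULL)
}

res <- rbind(
  run_scenario("null", function(s) big(s, theta = 0), 300),
  run_scenario("theta_0.2", function(s) big(1000 + s, theta = 0.2), 300),
  run_scenario("directional_pleiotropy",
               function(s) big(2000 + s, theta = 0.2, mu = 0.05,
                               sdev = 0.01), 300),
  run_scenario("inside_violated",
               function(s) big(3000 + s, theta = 0.2, mu = 0.05,
                               sdev = 0.02, inside = TRUE), 300),
  run_scenario("liver_scale_null",
               function(s) cohort_scenario("liver", seed = 4000 + s), 300))
write.table(res, "results/simulation_calibration.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

show <- function(scenario, estimator) {
  r <- res[res$scenario == scenario & res$estimator == estimator, ]
  sprintf("%.4f (sd %.4f)", r$mean, r$sd)
}
cat("IVW under the null:                 ", show("null", "ivw"), "\n")
cat("IVW at theta = 0.2:                 ", show("theta_0.2", "ivw"), "\n")
cat("IVW with directional pleiotropy:    ",
    show("directional_pleiotropy", "ivw"), " <- biased, as expected\n")
cat("Egger slope, same scenario:         ",
    show("directional_pleiotropy", "egger_slope"), "\n")
cat("Egger intercept, same scenario:     ",
    show("directional_pleiotropy", "egger_intercept"),
    " <- recovers mu = 0.05\n")
cat("Egger slope under InSIDE violation: ",
    show("inside_violated", "egger_slope"), " <- no longer unbiased\n")
cat("IVW spread at the liver scale:      ",
    show("liver_scale_null", "ivw"),
    " <- sampling sd ~0.3 log-OR: low power\n")
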