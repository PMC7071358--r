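#!/usr/bin/env Rscript
# Step 1: regenerate the pooled liver- and brain-cancer tables from the
# bundled published inputs and compare every cell with the printed value.
#
# Outputs: results/sensitivity_tables.tsv  (full recomputed grid)
#          results/published_comparison.tsv (cell-by-cell comparison)

library(ironmr)

dir.create("results", showWarnings = FALSE)

fix <- iron_fixtures()
plan <- analysis_plan(exposures = iron_traits,
                      outcomes = c("liver_cancer", "brain_cancer"),
                      methods = c("ivw-random", "weighted-median", "mr-egger"),
                      seed = 42L)
grid <- run_plan(plan, fix$harmonized)

# per-variant Wald ratios appended below the pooled rows, as in the
# published sensitivity tables
per_snp <- do.call(rbind, lapply(names(fix$harmonized), function(cell) {
  s <- fix$harmonized[[cell]]
  r <- single_variant_table(s)
  data.frame(exposure = attr(s, "exposure_id"),
             outcome = attr(s, "outcome_id"),
             instrument_set = attr(s, "label"),
             method = paste0("wald:", r$variant_id),
             n_variants = 1L, theta = r$theta, se = r$se,
             or = exp(r$theta),
             ci_low = exp(r$theta - 1.959964 * r$se),
             ci_high = exp(r$theta + 1.959964 * r$se),
             p = r$p, inflation = NA_real_)
}))
full <- rbind(grid, per_snp)
write.table(full, "results/sensitivity_tables.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cmp <- reproduce_published(seed = 42L)
write.table(cmp, "results/published_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ok_pts <- sum(cmp$point_ok)
cat(sprintf("recomputed %d pooled cells; %d/%d point estimates match the published values\n",
            nrow(cmp), ok_pts, nrow(cmp)))
flagged <- cmp[!cmp$point_ok, c("outcome", "exposure", "method", "or", "or_pub")]
if (nrow(flagged)) {
  cat("cells beyond tolerance (all brain-cancer MR-Egger; the printed\n",
      "per-variant inputs cannot regenerate these regressions - see the\n",
      "methods vignette):\n", sep = "")
  print(flagged, row.names = FALSE)
}
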