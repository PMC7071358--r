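#!/usr/bin/env Rscript
# Step 2: leave-one-out and HFE-exclusion sensitivity analyses. The
# published conclusion rests heavily on rs1800562 (HFE C282Y), the variant
# with the largest effect on iron status; this step quantifies how every
# pooled estimate moves when it (or any single variant) is removed.
#
# Output: results/leave_one_out.tsv

library(ironmr)

dir.create("results", showWarnings = FALSE)
fix <- iron_fixtures()

rows <- list()
for (cell in names(fix$harmonized)) {
  s <- fix$harmonized[[cell]]
  rep <- leave_one_out(s, method = "ivw-random", exclude = "rs1800562")
  for (id in names(rep$leave_one_out)) {
    est <- rep$leave_one_out[[id]]
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = attr(s, "outcome_id"), exposure = attr(s, "exposure_id"),
      removed = id, or = est$or_point, ci_low = est$or_low,
      ci_high = est$or_high, p = est$p)
  }
}
loo <- do.call(rbind, rows)
write.table(loo, "results/leave_one_out.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

full_sign <- vapply(names(fix$harmonized), function(cell) {
  sign(mr_ivw(wald_ratio(fix$harmonized[[cell]]))$theta_hat)
}, numeric(1))
no_hfe <- loo[loo$removed == "rs1800562", ]
crossing <- with(no_hfe, ci_low < 1 & ci_high > 1)
cat(sprintf("without rs1800562, %d/%d exposure-outcome estimates have a 95%% CI crossing OR = 1\n",
            sum(crossing), nrow(no_hfe)))
same_dir <- sign(log(no_hfe$or)) ==
  full_sign[paste(no_hfe$outcome, no_hfe$exposure, sep = ".")]
cat(sprintf("the effect direction of the full 3-variant estimate is preserved in %d/%d cells\n",
            sum(same_dir), length(same_dir)))
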