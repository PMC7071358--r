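#!/usr/bin/env Rscript
# Step 4: analytic power of the two-sample design for the cancer sites
# with bundled fixtures, across hypothesized odds ratios per SD and the
# variance explained by each biomarker's instruments.
#
# Output: results/power_grid.tsv

library(ironmr)

dir.create("results", showWarnings = FALSE)

sites <- data.frame(site = c("liver", "brain", "overall"),
                    cases = c(324, 810, 75037))
r2 <- c(serum_iron = 0.034, transferrin_saturation = 0.069,
        log10_ferritin = 0.009, transferrin = 0.072)
ors <- c(1.25, 1.5, 2, 2.45)
n <- 367643

grid <- expand.grid(site = sites$site, exposure = names(r2), or = ors,
                    stringsAsFactors = FALSE)
grid$cases <- sites$cases[match(grid$site, sites$site)]
grid$r2 <- r2[grid$exposure]
grid$power <- mr_power_binary(n, cases = grid$cases, r2 = grid$r2,
                              or_per_sd = grid$or)
write.table(grid, "results/power_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

liver_iron <- grid[grid$site == "liver" & grid$exposure == "serum_iron", ]
cat("power at the liver scale, serum iron instruments (r2 = 3.4%):\n")
print(liver_iron[, c("or", "power")], row.names = FALSE)
cat(sprintf("\npower is %.2f at OR 1.5 but %.2f at the observed point estimate of 2.45:\n",
            liver_iron$power[liver_iron$or == 1.5],
            liver_iron$power[liver_iron$or == 2.45]))
cat("moderate effects are easy to miss at 324 cases, matching the wide CIs\n")
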