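fix <- iron_fixtures()
instruments_path <- system.file("extdata", "iron_gwas_instruments.tsv",
                                package = "ironmr")

test_that("association tables read, filter by trait, and validate", {
  tab <- read_association_table(instruments_path,
                                column_map = c(trait = "trait_id"),
                                trait_id = "serum_iron")
  expect_s3_class(tab, "instrument_table")
  expect_equal(nrow(tab), 5L)
  hfe <- tab[tab$variant_id == "rs1800562", ]
  expect_equal(hfe$beta, 0.328)
  expect_equal(hfe$se, 0.016)
  expect_equal(hfe$effect_allele, "A")
  expect_equal(hfe$eaf, 0.07)

  # header-only file gives an empty table, not an error
  empty <- tempfile(fileext = ".tsv")
  writeLines("variant_id\teffect_allele\tbeta\tse", empty)
  expect_equal(nrow(read_association_table(empty, trait_id = "t")), 0L)

  # invariant violations are named, not silently dropped
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\teffect_allele\tbeta\tse",
               "rs1\tA\t0.1\t0"), bad)
  expect_error(read_association_table(bad, trait_id = "t"), "se must be > 0")
  writeLines(c("variant_id\teffect_allele\tbeta\tse",
               "rs1\tA\tabc\t0.1"), bad)
  expect_error(read_association_table(bad, trait_id = "t"), "non-numeric")
  writeLines(c("variant_id\teffect_allele\tbeta\tse",
               "rs1\tA\t0.1\t0.1", "rs1\tA\t0.2\t0.1"), bad)
  expect_error(read_association_table(bad, trait_id = "t"), "duplicate")
  writeLines(c("variant_id\teffect_allele\tbeta\tse",
               "rs1\tA\tNA\t0.1", "rs2\tA\t0.2\t0.1"), bad)
  expect_error(read_association_table(bad, trait_id = "t"), "missing beta")
  expect_message(
    ok <- read_association_table(bad, trait_id = "t", permissive = TRUE),
    "dropping")
  expect_equal(ok$variant_id, "rs2")

  # a column map is mandatory for renamed mandatory fields
  writeLines(c("snp\teffect_allele\tbeta\tse", "rs1\tA\t0.1\t0.1"), bad)
  expect_error(read_association_table(bad, trait_id = "t"), "mandatory")
  remapped <- read_association_table(bad, column_map = c(variant_id = "snp"),
                                     trait_id = "t")
  expect_equal(remapped$variant_id, "rs1")
})

test_that("sub-underflow p-values are floored at the smallest double", {
  tab <- read_association_table(instruments_path,
                                column_map = c(trait = "trait_id"),
                                trait_id = "transferrin")
  p_tf <- tab$pvalue[tab$variant_id == "rs8177240"]  # printed 8.4e-610
  expect_gt(p_tf, 0)
  expect_lt(p_tf, 1e-300)
})

test_that("instrument selection applies p and r-squared thresholds", {
  iron <- fix$exposures$serum_iron
  expect_warning(kept <- select_instruments(iron), "assumed independent")
  expect_equal(kept$variant_id, iron$variant_id)  # all genome-wide significant

  # dominance between perfectly correlated variants
  two <- instrument_table(
    data.frame(variant_id = c("rsA", "rsB"), effect_allele = "A",
               beta = c(0.1, 0.1), se = c(0.01, 0.01),
               pvalue = c(1e-10, 1e-9)), trait_id = "t")
  r2 <- matrix(c(1, 1, 1, 1), 2, 2,
               dimnames = list(c("rsA", "rsB"), c("rsA", "rsB")))
  expect_equal(select_instruments(two, correlations = r2)$variant_id, "rsA")
  expect_error(
    select_instruments(two, correlations = matrix(1, 1, 1,
                                                  dimnames = list("rsA", "rsA"))),
    "lacks variant")

  # a drastic threshold retains only the strongest association per trait
  suppressWarnings({
    ts <- select_instruments(fix$exposures$transferrin_saturation,
                             p_threshold = 1e-200)
    tf <- select_instruments(fix$exposures$transferrin,
                             p_threshold = 1e-200)
  })
  expect_equal(ts$variant_id, "rs1800562")   # p = 2.2e-270
  expect_equal(tf$variant_id, "rs8177240")   # p = 8.4e-610

  # loosening thresholds to (1, 1.01) is a no-op subset
  suppressWarnings(
    loose <- select_instruments(iron, p_threshold = 1 - 1e-12,
                                r2_threshold = 1.01))
  expect_equal(as.data.frame(loose), as.data.frame(iron))
})

test_that("harmonization aligns alleles across orientations and strands", {
  exp_tab <- instrument_table(
    data.frame(variant_id = c("rs1", "rs2", "rs3"),
               effect_allele = c("A", "A", "A"),
               other_allele = c("G", "G", "G"),
               beta = c(0.328, 0.2, 0.15), se = c(0.016, 0.01, 0.01)),
    trait_id = "expo")
  out_tab <- instrument_table(
    data.frame(variant_id = c("rs1", "rs2", "rs3"),
               effect_allele = c("G", "A", "T"),
               other_allele = c("A", "G", "C"),
               beta = c(0.5, 0.3, 0.2), se = c(0.1, 0.1, 0.1)),
    trait_id = "out")
  h <- harmonize(exp_tab, out_tab)
  # swapped alleles: sign inverted; identical orientation: untouched;
  # opposite strand (T/C vs A/G): same orientation, untouched
  expect_equal(h$beta_outcome, c(-0.5, 0.3, 0.2))
  expect_equal(h$flipped, c(TRUE, FALSE, FALSE))

  # idempotence: harmonizing the aligned outcome again changes nothing
  realigned <- instrument_table(
    data.frame(variant_id = h$variant_id, effect_allele = "A",
               other_allele = "G", beta = h$beta_outcome,
               se = h$se_outcome), trait_id = "out")
  h2 <- harmonize(exp_tab, realigned)
  expect_equal(h2$beta_outcome, h$beta_outcome)
  expect_false(any(h2$flipped))

  expect_error(
    harmonize(exp_tab,
              instrument_table(
                data.frame(variant_id = "rs1", effect_allele = "C",
                           other_allele = "A", beta = 1, se = 1),
                trait_id = "out")),
    "incompatible alleles for variant rs1")
})

test_that("palindromic variants follow the configured policy", {
  pal_exp <- instrument_table(
    data.frame(variant_id = "rs1799945", effect_allele = "C",
               other_allele = "G", eaf = 0.15, beta = 0.189, se = 0.010),
    trait_id = "expo")
  make_out <- function(eaf) instrument_table(
    data.frame(variant_id = "rs1799945", effect_allele = "C",
               other_allele = "G", eaf = eaf, beta = 0.4, se = 0.1),
    trait_id = "out")

  # frequencies on the same side, both informative: retained without flip
  h <- harmonize(pal_exp, make_out(0.14), policy = "eaf", eaf_window = 0.08)
  expect_false(h$flipped)
  expect_true(h$palindromic_flag)
  expect_equal(h$beta_outcome, 0.4)

  # opposite sides: flipped
  h_flip <- harmonize(pal_exp, make_out(0.86), policy = "eaf")
  expect_true(h_flip$flipped)
  expect_equal(h_flip$beta_outcome, -0.4)

  # ambiguous frequency near 0.5: excluded -> empty set errors
  expect_error(
    suppressMessages(harmonize(pal_exp, make_out(0.47), policy = "eaf")),
    "no variants survived")
  expect_error(harmonize(pal_exp, make_out(0.14), policy = "strict"),
               "palindromic")
  expect_error(
    suppressMessages(harmonize(pal_exp, make_out(0.14), policy = "drop")),
    "no variants survived")
})

test_that("double allele flip on both tables is an identity", {
  flip_table <- function(tab) {
    x <- as.data.frame(tab)
    x[, c("effect_allele", "other_allele")] <-
      x[, c("other_allele", "effect_allele")]
    x$beta <- -x$beta
    if (any(!is.na(x$eaf))) x$eaf <- 1 - x$eaf
    instrument_table(x, trait_id = attr(tab, "trait_id"))
  }
  exp_tab <- instrument_table(
    data.frame(variant_id = c("rs1", "rs2"), effect_allele = c("A", "C"),
               other_allele = c("G", "T"), eaf = c(0.2, 0.7),
               beta = c(0.3, -0.1), se = c(0.02, 0.03)), trait_id = "expo")
  out_tab <- instrument_table(
    data.frame(variant_id = c("rs1", "rs2"), effect_allele = c("G", "C"),
               other_allele = c("A", "T"), eaf = c(0.8, 0.7),
               beta = c(0.5, 0.25), se = c(0.1, 0.1)), trait_id = "out")
  h1 <- harmonize(exp_tab, out_tab)
  h2 <- harmonize(flip_table(exp_tab), flip_table(out_tab))
  # exposure orientation flips with its table; effect directions agree
  expect_equal(h2$beta_outcome / h2$beta_exposure,
               h1$beta_outcome / h1$beta_exposure)
  expect_equal(abs(h2$beta_outcome), abs(h1$beta_outcome))
})

test_that("back-derivation from odds-ratio tables inverts the Wald ratio", {
  # frozen from direct evaluation of ln and the CI-width formula
  bf <- backfill_from_ratio(0.27, 0.15, 0.50, beta_exposure = -0.479)
  expect_equal(bf$gamma / -0.479, -1.3093333, tolerance = 1e-6)
  expect_equal(bf$se_gamma / 0.479, 0.3071417, tolerance = 1e-6)
  bf2 <- backfill_from_ratio(6.65, 2.78, 15.9, beta_exposure = 0.328)
  expect_equal(bf2$gamma / 0.328, 1.8946169, tolerance = 1e-6)
  expect_equal(bf2$se_gamma / 0.328, 0.4448724, tolerance = 1e-6)

  expect_error(backfill_from_ratio(1, 1, 1, 0.328), "degenerate")
  expect_error(backfill_from_ratio(0.5, 0.6, 0.7, 0.3), "ci_low <= or_point")
  expect_error(backfill_from_ratio(1.2, -0.1, 2, 0.3), "positive")
  expect_error(backfill_from_ratio(1.2, 1.0, 2, 0), "nonzero")

  # round trip: the Wald ratio recovers the printed OR and CI to < 0.5%
  # on the log scale (printed triples whose CI is log-symmetric; coarser
  # prints like (0.15, 0.50) carry asymmetric rounding beyond that)
  for (or_row in list(c(6.65, 2.78, 15.9), c(1.54, 0.65, 3.64),
                      exp(c(0.4, 0.4 - 1.959964 * 0.3, 0.4 + 1.959964 * 0.3)))) {
    bf <- backfill_from_ratio(or_row[1], or_row[2], or_row[3], 0.25)
    s <- make_set(0.25, 0.01, bf$gamma, bf$se_gamma)
    r <- wald_ratio(s)
    got <- c(exp(r$theta), exp(r$theta - 1.959964 * r$se),
             exp(r$theta + 1.959964 * r$se))
    expect_equal(log(got), log(or_row), tolerance = 0.005)
  }
})

test_that("bundled fixtures carry the published study inputs", {
  expect_named(fix$exposures, iron_traits)
  expect_equal(vapply(fix$exposures, nrow, 1L),
               c(serum_iron = 5L, transferrin_saturation = 5L,
                 log10_ferritin = 6L, transferrin = 8L))
  expect_length(fix$harmonized, 8L)
  expect_true(all(vapply(fix$harmonized, nrow, 1L) == 3L))

  iron <- fix$exposures$serum_iron
  expect_equal(iron$beta[iron$variant_id == "rs855791"], 0.181)
  expect_equal(iron$se[iron$variant_id == "rs855791"], 0.007)
  expect_equal(attr(iron, "variance_explained"), 0.034)

  # every per-variant transferrin-liver OR is below 1, so all three Wald
  # ratios are negative; with negative exposure betas the aligned outcome
  # log-odds are positive
  tf_liver <- fix$harmonized[["liver_cancer.transferrin"]]
  expect_equal(tf_liver$variant_id, primary_snps)
  expect_true(all(wald_ratio(tf_liver)$theta < 0))
  expect_true(all(tf_liver$beta_exposure < 0))
  expect_true(all(tf_liver$beta_outcome > 0))
})
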