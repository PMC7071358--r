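# Bundled published summary statistics: the iron-status GWAS instrument
# table (Genetics of Iron Status Consortium, n = 48,972) and the UK Biobank
# per-variant liver and brain cancer odds ratios from which the outcome
# log-odds associations are back-derived.

#' The three variants used as primary iron-status instruments
#'
#' rs1800562 and rs1799945 in *HFE* and rs855791 in *TMPRSS6*: mutually
#' uncorrelated (r-squared < 0.01) and jointly responsible for most of the
#' instrumented variance in each iron biomarker.
#' @export
primary_snps <- c("rs1800562", "rs1799945", "rs855791")

#' Trait identifiers of the four iron-status biomarkers
#' @export
iron_traits <- c("serum_iron", "transferrin_saturation",
                 "log10_ferritin", "transferrin")

# instruments jointly explain 3.4% (iron), 7.2% (transferrin),
# 6.9% (saturation) and 0.9% (ferritin) of biomarker variance
.variance_explained <- c(serum_iron = 0.034,
                         transferrin_saturation = 0.069,
                         log10_ferritin = 0.009,
                         transferrin = 0.072)

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "ironmr")
  if (path == "") stop("bundled file not found: ", file, call. = FALSE)
  path
}

#' Bundled published instrument tables and harmonized cancer sets
#'
#' Loads the packaged plain-text fixtures and returns the study inputs of
#' the iron-status cancer analysis: the four exposure instrument tables
#' (serum iron and transferrin saturation with 5 variants each, log10
#' ferritin with 6, serum transferrin with 8, all in SD units from a GWAS of
#' 48,972 European-descent individuals) and, for each biomarker, the
#' three-variant harmonized sets against liver cancer and brain cancer.
#' Outcome log-odds ratios are back-derived from the published per-variant
#' odds ratios and 95% CIs via [backfill_from_ratio()]; alleles are aligned
#' by construction because both sides are expressed on the same effect
#' allele.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{exposures}{named list of four [instrument_table()]s;}
#'     \item{harmonized}{named list of eight [harmonized_set()]s, names of
#'       the form `"<outcome>.<exposure>"` (e.g. `"liver_cancer.serum_iron"`),
#'       each restricted to the three primary variants;}
#'     \item{per_snp_or}{data frame of the published per-variant odds ratios
#'       used for the back-derivation.}
#'   }
#' @export
iron_fixtures <- function() {
  instruments <- utils::read.table(extdata_path("iron_gwas_instruments.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE,
                                   na.strings = "NA")
  # the transferrin lead SNP p-value underflows double precision as printed
  instruments$pvalue[instruments$pvalue == 0] <- .Machine$double.xmin
  exposures <- lapply(iron_traits, function(trait) {
    rows <- instruments[instruments$trait_id == trait, , drop = FALSE]
    rownames(rows) <- NULL
    instrument_table(rows, trait_id = trait,
                     variance_explained = unname(.variance_explained[trait]))
  })
  names(exposures) <- iron_traits

  per_snp <- utils::read.table(extdata_path("cancer_per_snp_or.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  harmonized <- list()
  for (outcome in unique(per_snp$outcome_id)) {
    for (trait in iron_traits) {
      exp_tab <- exposures[[trait]]
      exp_rows <- as.data.frame(exp_tab)[
        match(primary_snps, exp_tab$variant_id), ]
      or_rows <- per_snp[per_snp$outcome_id == outcome &
                           per_snp$exposure_id == trait, ]
      or_rows <- or_rows[match(primary_snps, or_rows$variant_id), ]
      bf <- backfill_from_ratio(or_rows$or, or_rows$ci_low, or_rows$ci_high,
                                exp_rows$beta)
      harmonized[[paste(outcome, trait, sep = ".")]] <- harmonized_set(
        data.frame(variant_id = primary_snps,
                   beta_exposure = exp_rows$beta,
                   se_exposure = exp_rows$se,
                   beta_outcome = bf$gamma,
                   se_outcome = bf$se_gamma,
                   stringsAsFactors = FALSE),
        exposure_id = trait, outcome_id = outcome, label = "primary-3snp")
    }
  }
  list(exposures = exposures, harmonized = harmonized, per_snp_or = per_snp)
}

#' Published pooled estimates for the liver and brain cancer analyses
#'
#' The published inverse-variance-weighted, weighted-median and MR-Egger
#' odds ratios (with 95% CIs and p-values) for the four iron biomarkers
#' against liver and brain cancer, as a tidy data frame. Used by
#' [reproduce_published()] to flag any recomputed cell that deviates from
#' the printed value.
#' @return A data frame with columns `outcome_id`, `exposure_id`, `method`,
#'   `or`, `ci_low`, `ci_high`, `pvalue`.
#' @export
published_estimates <- function() {
  utils::read.table(extdata_path("published_pooled_estimates.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
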