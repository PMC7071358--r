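# Data model and plumbing for summary-level association statistics:
# instrument tables, allele harmonization, and back-derivation of outcome
# log-odds ratios from published per-variant odds-ratio tables.

# 97.5% normal quantile used for every 95% interval in the package.
Z95 <- 1.959964

.assoc_cols <- c("variant_id", "gene", "effect_allele", "other_allele",
                 "eaf", "trait_id", "beta", "se", "pvalue", "n")

#' Construct an instrument table
#'
#' An instrument table holds one row per genetic variant with its association
#' to a single trait: effect size `beta` (SD units for continuous traits,
#' log-odds per effect allele for binary ones), standard error `se`, effect
#' allele and, when known, the other allele and effect-allele frequency.
#'
#' @param x A data frame with at least `variant_id`, `effect_allele`,
#'   `beta` and `se` columns. Optional columns: `gene`, `other_allele`,
#'   `eaf`, `pvalue`, `n`.
#' @param trait_id Trait identifier shared by all rows.
#' @param variance_explained Optional fraction of trait variance explained by
#'   the instruments jointly, in `[0, 1]`.
#' @return A data frame of class `instrument_table` with attributes
#'   `trait_id` and `variance_explained`.
#' @export
instrument_table <- function(x, trait_id, variance_explained = NA_real_) {
  stopifnot(is.data.frame(x), is.character(trait_id), length(trait_id) == 1L)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in setdiff(.assoc_cols, names(x))) {
    filler <- if (col %in% c("eaf", "beta", "se", "pvalue", "n"))
      NA_real_ else NA_character_
    x[[col]] <- rep(filler, nrow(x))
  }
  x$trait_id <- rep(trait_id, nrow(x))
  x <- x[, .assoc_cols]
  validate_associations(x)
  if (!is.na(variance_explained) &&
      (variance_explained < 0 || variance_explained > 1)) {
    stop("`variance_explained` must lie in [0, 1]", call. = FALSE)
  }
  structure(x,
            trait_id = trait_id,
            variance_explained = variance_explained,
            class = c("instrument_table", "data.frame"))
}

#' @export
print.instrument_table <- function(x, ...) {
  cat(sprintf("Instrument table: %s (%d variant%s)\n",
              attr(x, "trait_id"), nrow(x), if (nrow(x) == 1L) "" else "s"))
  ve <- attr(x, "variance_explained")
  if (!is.na(ve)) cat(sprintf("Variance explained: %.1f%%\n", 100 * ve))
  print(as.data.frame(x), ...)
  invisible(x)
}

# Shared invariants for association rows; errors name the offending row.
validate_associations <- function(x) {
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("%s (row%s %s, variant%s %s)", what,
                   if (length(idx) > 1L) "s" else "",
                   paste(idx, collapse = ", "),
                   if (length(idx) > 1L) "s" else "",
                   paste(x$variant_id[idx], collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(is.na(x$beta), "missing beta")
  bad(is.na(x$se), "missing se")
  bad(!is.na(x$se) & x$se <= 0, "se must be > 0")
  bad(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1),
      "eaf must lie strictly inside (0, 1)")
  bad(!is.na(x$pvalue) & (x$pvalue <= 0 | x$pvalue > 1),
      "pvalue must lie in (0, 1]")
  key <- paste(x$variant_id, x$trait_id)
  bad(duplicated(key), "duplicate (variant_id, trait_id)")
  invisible(x)
}

#' Read a summary-association table from a delimited file
#'
#' Parses a tab- or comma-separated file with a header row into an
#' [instrument_table()]. Parsing is locale-independent (decimal point).
#' P-values printed below the double-precision underflow limit (for example
#' `8.4e-610`) are floored at the smallest representable positive double
#' rather than collapsing to zero.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical field names
#'   (`variant_id`, `effect_allele`, `beta`, `se`, and optionally `gene`,
#'   `other_allele`, `eaf`, `pvalue`, `n`) to column names in the file.
#'   Fields absent from the map are taken from identically named columns
#'   when present.
#' @param trait_id Trait identifier to assign (or, when the file has a
#'   `trait` column mapped, the value to filter on).
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @param permissive If `TRUE`, rows with missing `beta` or `se` are dropped
#'   with a message instead of raising an error.
#' @return An [instrument_table()].
#' @export
read_association_table <- function(path, column_map = NULL, trait_id,
                                   sep = "\t", permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), dec = ".",
                           stringsAsFactors = FALSE)
  pick <- function(field) {
    src <- if (!is.null(column_map) && field %in% names(column_map))
      column_map[[field]] else field
    if (!src %in% names(raw)) return(NULL)
    raw[[src]]
  }
  mandatory <- c("variant_id", "effect_allele", "beta", "se")
  for (field in mandatory) {
    if (is.null(pick(field))) {
      stop("mandatory column not found for field `", field, "`", call. = FALSE)
    }
  }
  num <- function(field) {
    txt <- pick(field)
    if (is.null(txt)) return(rep(NA_real_, nrow(raw)))
    val <- suppressWarnings(as.numeric(txt))
    garbled <- !is.na(txt) & is.na(val)
    if (any(garbled)) {
      stop(sprintf("non-numeric %s at row%s %s", field,
                   if (sum(garbled) > 1L) "s" else "",
                   paste(which(garbled), collapse = ", ")), call. = FALSE)
    }
    # positive literals below ~1e-308 underflow to 0; keep them positive
    under <- !is.na(val) & val == 0 & grepl("[1-9]", txt)
    val[under] <- .Machine$double.xmin
    val
  }
  out <- data.frame(variant_id = pick("variant_id"),
                    gene = pick("gene") %||% rep(NA_character_, nrow(raw)),
                    effect_allele = toupper(pick("effect_allele")),
                    other_allele = toupper(pick("other_allele") %||%
                                             rep(NA_character_, nrow(raw))),
                    eaf = num("eaf"),
                    beta = num("beta"),
                    se = num("se"),
                    pvalue = num("pvalue"),
                    n = num("n"),
                    stringsAsFactors = FALSE)
  trait_col <- pick("trait")
  if (!is.null(trait_col)) out <- out[trait_col == trait_id, , drop = FALSE]
  incomplete <- is.na(out$beta) | is.na(out$se)
  if (any(incomplete)) {
    if (!permissive) {
      stop(sprintf("missing beta/se at row%s %s; set permissive = TRUE to drop",
                   if (sum(incomplete) > 1L) "s" else "",
                   paste(which(incomplete), collapse = ", ")), call. = FALSE)
    }
    message("dropping ", sum(incomplete), " row(s) with missing beta/se")
    out <- out[!incomplete, , drop = FALSE]
  }
  rownames(out) <- NULL
  instrument_table(out, trait_id = trait_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select independent genome-wide-significant instruments
#'
#' Keeps variants whose association p-value passes `p_threshold`, then prunes
#' correlated pairs: among variants with pairwise r-squared at or above
#' `r2_threshold`, the one with the smaller p-value is retained (ties broken
#' by smaller standard error, then lexicographic variant id). When no
#' correlation matrix is supplied all variants are assumed independent and a
#' warning is issued.
#'
#' @param table An [instrument_table()].
#' @param p_threshold Significance threshold in `(0, 1)`; the genome-wide
#'   convention is `5e-8`.
#' @param r2_threshold Pairwise r-squared above which two variants are
#'   considered correlated; `0.01` by default.
#' @param correlations Optional symmetric matrix of pairwise r-squared values
#'   with variant ids as dimnames, covering every retained pair.
#' @return The filtered [instrument_table()], in the input row order.
#' @export
select_instruments <- function(table, p_threshold = 5e-8,
                               r2_threshold = 0.01, correlations = NULL) {
  stopifnot(inherits(table, "instrument_table"))
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("`p_threshold` must lie in (0, 1)", call. = FALSE)
  }
  keep <- !is.na(table$pvalue) & table$pvalue < p_threshold
  x <- as.data.frame(table)[keep, , drop = FALSE]
  if (is.null(correlations)) {
    if (nrow(x) > 1L) {
      warning("no correlation matrix supplied; variants assumed independent",
              call. = FALSE)
    }
  } else if (nrow(x) > 1L) {
    ids <- x$variant_id
    missing_ids <- setdiff(ids, rownames(correlations))
    if (length(missing_ids)) {
      stop("correlation matrix lacks variant(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    # greedy dominance: best variant first, drop anything correlated with it
    ord <- order(x$pvalue, x$se, x$variant_id)
    kept <- character(0)
    for (id in ids[ord]) {
      r2 <- if (length(kept)) correlations[id, kept] else numeric(0)
      if (all(r2 < r2_threshold)) kept <- c(kept, id)
    }
    x <- x[x$variant_id %in% kept, , drop = FALSE]
  }
  rownames(x) <- NULL
  instrument_table(x, trait_id = attr(table, "trait_id"),
                   variance_explained = attr(table, "variance_explained"))
}

strand_complement <- function(allele) {
  ifelse(is.na(allele), NA_character_,
         chartr("ACGT", "TGCA", allele))
}

is_palindromic <- function(ea, oa) {
  !is.na(ea) & !is.na(oa) & oa == strand_complement(ea)
}

#' Construct a harmonized exposure-outcome variant set
#'
#' @param pairs Data frame with columns `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` and optionally `flipped`,
#'   `palindromic_flag`.
#' @param exposure_id,outcome_id Trait identifiers.
#' @param label Instrument-set label, e.g. `"primary-3snp"` or `"all-snp"`.
#' @return A data frame of class `harmonized_set`.
#' @export
harmonized_set <- function(pairs, exposure_id, outcome_id,
                           label = "custom") {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1L)
  if (!"flipped" %in% names(pairs)) pairs$flipped <- FALSE
  if (!"palindromic_flag" %in% names(pairs)) pairs$palindromic_flag <- FALSE
  need <- c("variant_id", "beta_exposure", "se_exposure",
            "beta_outcome", "se_outcome", "flipped", "palindromic_flag")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pairs <- as.data.frame(pairs)[, need]
  if (anyDuplicated(pairs$variant_id)) {
    stop("duplicate variant_id in harmonized set", call. = FALSE)
  }
  if (any(pairs$se_exposure <= 0) || any(pairs$se_outcome <= 0)) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  rownames(pairs) <- NULL
  structure(pairs, exposure_id = exposure_id, outcome_id = outcome_id,
            label = label, class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s [%s], %d variant%s\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"),
              attr(x, "label"), nrow(x), if (nrow(x) == 1L) "" else "s"))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Align outcome effect alleles to the exposure orientation
#'
#' Matches variants present in both tables, flips outcome effects reported on
#' the opposite allele (including across strand conventions, A<->T / C<->G),
#' and resolves palindromic variants (A/T or C/G) according to `policy`:
#' `"strict"` raises an error, `"drop"` excludes them with a message, and
#' `"eaf"` aligns by effect-allele-frequency side provided both frequencies
#' fall outside `0.5 +/- eaf_window` (same side: keep; opposite sides: flip;
#' either ambiguous: exclude).
#'
#' When one table omits the other allele, orientation is inferred from the
#' effect allele alone; an effect-allele mismatch is then an error because a
#' swap cannot be distinguished from a strand difference.
#'
#' @param exposure,outcome [instrument_table()]s indexed by `variant_id`.
#' @param policy Palindromic-variant policy: `"eaf"` (default), `"strict"`,
#'   or `"drop"`.
#' @param eaf_window Half-width of the ambiguity zone around frequency 0.5
#'   used by the `"eaf"` policy; default 0.08.
#' @param label Instrument-set label carried into the result.
#' @return A [harmonized_set()] in exposure-table row order.
#' @export
harmonize <- function(exposure, outcome, policy = c("eaf", "strict", "drop"),
                      eaf_window = 0.08, label = "custom") {
  policy <- match.arg(policy)
  stopifnot(inherits(exposure, "instrument_table"),
            inherits(outcome, "instrument_table"))
  shared <- exposure$variant_id[exposure$variant_id %in% outcome$variant_id]
  if (!length(shared)) stop("no shared variants", call. = FALSE)
  o <- as.data.frame(outcome)
  rownames(o) <- o$variant_id
  rows <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    id <- shared[k]
    e <- as.data.frame(exposure)[exposure$variant_id == id, ]
    u <- o[id, ]
    pal <- is_palindromic(e$effect_allele, e$other_allele) ||
      is_palindromic(u$effect_allele, u$other_allele)
    if (pal) {
      if (policy == "strict") {
        stop("palindromic variant ", id, " under strict policy", call. = FALSE)
      }
      if (policy == "drop") {
        message("dropping palindromic variant ", id)
        next
      }
      if (is.na(e$eaf) || is.na(u$eaf) ||
          abs(e$eaf - 0.5) <= eaf_window || abs(u$eaf - 0.5) <= eaf_window) {
        message("excluding palindromic variant ", id,
                " (allele frequency uninformative)")
        next
      }
      flip <- (e$eaf < 0.5) != (u$eaf < 0.5)
    } else {
      oa_known <- !is.na(e$other_allele) && !is.na(u$other_allele)
      if (oa_known) {
        # a single strand interpretation must explain both alleles
        same_id <- u$effect_allele == e$effect_allele &&
          u$other_allele == e$other_allele
        comp_id <- u$effect_allele == strand_complement(e$effect_allele) &&
          u$other_allele == strand_complement(e$other_allele)
        same_swap <- u$effect_allele == e$other_allele &&
          u$other_allele == e$effect_allele
        comp_swap <- u$effect_allele == strand_complement(e$other_allele) &&
          u$other_allele == strand_complement(e$effect_allele)
        if (same_id || comp_id) {
          flip <- FALSE
        } else if (same_swap || comp_swap) {
          flip <- TRUE
        } else {
          stop("incompatible alleles for variant ", id, call. = FALSE)
        }
      } else {
        # effect allele only: a swap cannot be told from a strand change
        if (u$effect_allele == e$effect_allele ||
            u$effect_allele == strand_complement(e$effect_allele)) {
          flip <- FALSE
        } else {
          stop("incompatible alleles for variant ", id, call. = FALSE)
        }
      }
    }
    rows[[k]] <- data.frame(
      variant_id = id,
      beta_exposure = e$beta,
      se_exposure = e$se,
      beta_outcome = if (flip) -u$beta else u$beta,
      se_outcome = u$se,
      flipped = flip,
      palindromic_flag = pal,
      stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no variants survived harmonization", call. = FALSE)
  harmonized_set(do.call(rbind, rows),
                 exposure_id = attr(exposure, "trait_id"),
                 outcome_id = attr(outcome, "trait_id"),
                 label = label)
}

#' Back-derive an outcome association from a published odds ratio
#'
#' Published per-variant causal odds ratios are first-order Wald ratios
#' `exp(gamma / beta)`. Given the printed point estimate and 95% CI (normal
#' on the log scale) together with the exposure beta, this inverts that
#' mapping: `theta = ln(OR)`, `se_theta = (ln U - ln L) / (2 * 1.959964)`,
#' then `gamma = theta * beta` and `se_gamma = se_theta * |beta|`.
#'
#' @param or_point,ci_low,ci_high Odds ratio and its 95% CI bounds, with
#'   `0 < ci_low <= or_point <= ci_high` and `ci_low < ci_high`.
#' @param beta_exposure Exposure effect in SD units; must be nonzero.
#' @return A list with elements `gamma` and `se_gamma` (vectorized).
#' @export
backfill_from_ratio <- function(or_point, ci_low, ci_high, beta_exposure) {
  if (any(ci_low <= 0) || any(or_point <= 0) || any(ci_high <= 0)) {
    stop("odds ratios and CI bounds must be positive", call. = FALSE)
  }
  if (any(ci_low > or_point) || any(or_point > ci_high)) {
    stop("need ci_low <= or_point <= ci_high", call. = FALSE)
  }
  if (any(beta_exposure == 0)) {
    stop("`beta_exposure` must be nonzero", call. = FALSE)
  }
  theta <- log(or_point)
  se_theta <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  if (any(se_theta <= 0)) {
    stop("degenerate (zero-width) confidence interval", call. = FALSE)
  }
  list(gamma = theta * beta_exposure, se_gamma = se_theta * abs(beta_exposure))
}
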