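# GWAS summary-statistics container, readers/writers, and allele harmonization.
#
# The canonical per-variant record holds: variant_id, chrom, pos (1-based),
# effect_allele, other_allele, eaf, beta, se, pvalue, n, n_case, n_control.
# Effect sizes are log-odds ratios for case-control traits and per-SD units
# for quantitative (protein) traits.

SUMSTATS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pvalue",
                      "n", "n_case", "n_control")

SUMSTATS_MANDATORY <- c("variant_id", "chrom", "pos", "effect_allele",
                        "other_allele", "beta", "se", "pvalue")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics object
#'
#' Bundles a per-variant association table with trait metadata. Rows violating
#' the record invariants (non-positive standard error, allele not a single
#' A/C/G/T base, identical alleles, frequency outside \[0, 1\], position < 1,
#' p-value outside (0, 1\]) are removed; the number removed is kept in the
#' `n_rejected` attribute and reported, never silently dropped.
#'
#' @param records data.frame with (a subset of) the canonical columns
#'   `variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#'   pvalue, n, n_case, n_control`.
#' @param trait_id character label for the trait.
#' @param trait_type `"quantitative"` (protein levels, per-SD betas) or
#'   `"case_control"` (log-OR betas).
#' @param default_n,default_n_case,default_n_control fallback sample sizes
#'   used when a record carries no `n` (`n_case`/`n_control`) of its own.
#' @param verbose emit a message when rows are rejected.
#' @return An object of class `summary_stats`: a list with `trait_id`,
#'   `trait_type`, `records` (validated data.frame keyed by `variant_id`) and
#'   the default sizes.
#' @export
summary_stats <- function(records, trait_id = "trait",
                          trait_type = c("quantitative", "case_control"),
                          default_n = NA_real_, default_n_case = NA_real_,
                          default_n_control = NA_real_, verbose = FALSE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  for (col in setdiff(SUMSTATS_COLUMNS, names(records))) {
    records[[col]] <- if (col %in% c("variant_id", "chrom",
                                     "effect_allele", "other_allele"))
      NA_character_ else NA_real_
  }
  missing_cols <- SUMSTATS_MANDATORY[
    vapply(SUMSTATS_MANDATORY, function(cl) all(is.na(records[[cl]])),
           logical(1)) & nrow(records) > 0]
  if (length(missing_cols) > 0)
    stopf("summary statistics are missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  records <- records[SUMSTATS_COLUMNS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n", "n_case",
                "n_control"))
    records[[col]] <- as.numeric(records[[col]])

  ok <- !is.na(records$variant_id) & nzchar(records$variant_id) &
    records$effect_allele %in% VALID_ALLELES &
    records$other_allele %in% VALID_ALLELES &
    records$effect_allele != records$other_allele &
    !is.na(records$beta) & is.finite(records$beta) &
    !is.na(records$se) & records$se > 0 &
    !is.na(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1 &
    !is.na(records$pos) & records$pos >= 1 &
    (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1))
  n_rejected <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  if (anyDuplicated(records$variant_id))
    stopf("duplicate variant_id within trait '%s'", trait_id)
  rownames(records) <- NULL
  if (n_rejected > 0 && verbose)
    message(sprintf("summary_stats[%s]: rejected %d invalid row(s)",
                    trait_id, n_rejected))
  out <- structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records,
         default_n = default_n, default_n_case = default_n_case,
         default_n_control = default_n_control),
    class = "summary_stats")
  attr(out, "n_rejected") <- n_rejected
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s): %d variant(s)\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  if (!is.na(x$default_n))
    cat(sprintf("  default n = %s\n", format(x$default_n)))
  if (!is.na(x$default_n_case))
    cat(sprintf("  default cases/controls = %s/%s\n",
                format(x$default_n_case), format(x$default_n_control)))
  invisible(x)
}

#' Resolve per-record sample sizes against trait defaults
#'
#' @param ss `summary_stats`.
#' @return `ss` with `n` (and for case-control traits `n_case`/`n_control`)
#'   filled from the trait defaults where missing.
#' @export
resolve_n <- function(ss) {
  r <- ss$records
  r$n[is.na(r$n)] <- ss$default_n
  if (ss$trait_type == "case_control") {
    r$n_case[is.na(r$n_case)] <- ss$default_n_case
    r$n_control[is.na(r$n_control)] <- ss$default_n_control
    if (anyNA(r$n_case) || anyNA(r$n_control))
      stopf("case-control trait '%s': n_case/n_control unresolvable",
            ss$trait_id)
    r$n[is.na(r$n)] <- r$n_case[is.na(r$n)] + r$n_control[is.na(r$n)]
  }
  ss$records <- r
  ss
}

#' Read GWAS summary statistics from a delimited text file
#'
#' @param path file path to a delimited text table with a header row.
#' @param dialect named character vector mapping canonical field names to the
#'   source file's column names, e.g. `c(variant_id = "SNP", beta = "b")`.
#'   Canonical columns need no mapping.
#' @param sep field separator (default tab).
#' @inheritParams summary_stats
#' @return A [summary_stats] object.
#' @export
read_sumstats <- function(path, dialect = NULL, trait_id = basename(path),
                          trait_type = c("quantitative", "case_control"),
                          default_n = NA_real_, default_n_case = NA_real_,
                          default_n_control = NA_real_, sep = "\t",
                          verbose = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw))
        stopf("dialect maps '%s' to column '%s', absent from %s",
              canon, src, path)
      names(raw)[names(raw) == src] <- canon
    }
  }
  present <- intersect(SUMSTATS_COLUMNS, names(raw))
  missing_mand <- setdiff(SUMSTATS_MANDATORY, present)
  if (length(missing_mand) > 0)
    stopf("%s: missing mandatory column(s): %s (declare a dialect mapping?)",
          path, paste(missing_mand, collapse = ", "))
  ss <- summary_stats(raw[present], trait_id = trait_id,
                      trait_type = trait_type, default_n = default_n,
                      default_n_case = default_n_case,
                      default_n_control = default_n_control,
                      verbose = verbose)
  if (nrow(ss$records) == 0L)
    stopf("%s: zero valid summary-statistic rows", path)
  ss
}

#' Write summary statistics in the canonical tab-separated layout
#'
#' @param ss `summary_stats`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  utils::write.table(ss$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome records onto a common effect allele
#'
#' For each requested variant the outcome record is expressed on the exposure's
#' effect allele. Identically coded pairs pass through; swapped codings have
#' the outcome beta negated and frequency complemented (`flipped = TRUE`).
#' Palindromic (A/T, C/G) variants are strand-ambiguous: they are kept only
#' when both allele frequencies fall on the same side of 0.5 and both lie
#' outside the ambiguity band `[palindromic_eaf_limit, 1 - palindromic_eaf_limit]`
#' (missing frequencies drop the pair). Any other allele combination is
#' incompatible. Statuses are data, not errors.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param variant_ids variants to harmonize; default all exposure variants.
#'   Every requested id must be present in the exposure; ids absent from the
#'   outcome are returned with status `missing_outcome`.
#' @param palindromic_eaf_limit lower edge of the frequency ambiguity band
#'   (default 0.42, i.e. drop palindromic variants with eaf in \[0.42, 0.58\]).
#' @return data.frame of class `harmonized_pairs`, one row per requested
#'   variant: exposure fields (`beta_exp`, `se_exp`, ...), outcome fields
#'   expressed on the exposure effect allele (`beta_out`, `se_out`, ...),
#'   `flipped`, and `status` in `ok`, `dropped_palindromic`,
#'   `dropped_incompatible`, `missing_outcome`.
#' @export
harmonize <- function(exposure, outcome, variant_ids = NULL,
                      palindromic_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  stopifnot(palindromic_eaf_limit > 0, palindromic_eaf_limit < 0.5)
  exposure <- resolve_n(exposure)
  variant_ids <- variant_ids %||% exposure$records$variant_id
  missing_exp <- setdiff(variant_ids, exposure$records$variant_id)
  if (length(missing_exp) > 0)
    stopf("variant(s) absent from exposure: %s",
          paste(utils::head(missing_exp, 5), collapse = ", "))
  er <- exposure$records[match(variant_ids, exposure$records$variant_id), ]
  o_idx <- match(variant_ids, outcome$records$variant_id)

  out <- data.frame(
    variant_id = variant_ids, chrom = er$chrom, pos = er$pos,
    effect_allele = er$effect_allele, other_allele = er$other_allele,
    eaf_exp = er$eaf, beta_exp = er$beta, se_exp = er$se,
    pvalue_exp = er$pvalue, n_exp = er$n,
    eaf_out = NA_real_, beta_out = NA_real_, se_out = NA_real_,
    pvalue_out = NA_real_, n_out = NA_real_,
    n_case_out = NA_real_, n_control_out = NA_real_,
    flipped = FALSE, status = "missing_outcome",
    stringsAsFactors = FALSE)

  has_out <- !is.na(o_idx)
  if (any(has_out)) {
    outcome_res <- resolve_n_soft(outcome)
    or <- outcome_res$records[o_idx[has_out], ]
    i <- which(has_out)
    same <- or$effect_allele == er$effect_allele[i] &
      or$other_allele == er$other_allele[i]
    swapped <- or$effect_allele == er$other_allele[i] &
      or$other_allele == er$effect_allele[i]
    pal <- is_palindromic(er$effect_allele[i], er$other_allele[i])

    status <- rep("dropped_incompatible", length(i))
    flipped <- swapped & !same
    status[same | swapped] <- "ok"

    beta_out <- ifelse(flipped, -or$beta, or$beta)
    eaf_out <- ifelse(flipped, 1 - or$eaf, or$eaf)

    # palindromic: label-based orientation must be corroborated by frequency
    if (any(pal & status == "ok")) {
      j <- which(pal & status == "ok")
      e_eaf <- er$eaf[i][j]
      o_eaf <- eaf_out[j]
      keep <- !is.na(e_eaf) & !is.na(o_eaf) &
        sign(e_eaf - 0.5) == sign(o_eaf - 0.5) &
        abs(e_eaf - 0.5) > (0.5 - palindromic_eaf_limit) &
        abs(o_eaf - 0.5) > (0.5 - palindromic_eaf_limit)
      status[j][!keep] <- "dropped_palindromic"
    }

    out$eaf_out[i] <- eaf_out
    out$beta_out[i] <- beta_out
    out$se_out[i] <- or$se
    out$pvalue_out[i] <- or$pvalue
    out$n_out[i] <- or$n
    out$n_case_out[i] <- or$n_case
    out$n_control_out[i] <- or$n_control
    out$flipped[i] <- flipped
    out$status[i] <- status
    # dropped pairs carry no estimates downstream
    dropped <- i[status != "ok"]
    out[dropped, c("beta_out", "se_out", "pvalue_out")] <- NA_real_
    out$flipped[dropped] <- FALSE
  }
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

# resolve defaults without failing on quantitative traits lacking case counts
resolve_n_soft <- function(ss) {
  r <- ss$records
  r$n[is.na(r$n)] <- ss$default_n
  r$n_case[is.na(r$n_case)] <- ss$default_n_case
  r$n_control[is.na(r$n_control)] <- ss$default_n_control
  miss <- is.na(r$n) & !is.na(r$n_case) & !is.na(r$n_control)
  r$n[miss] <- r$n_case[miss] + r$n_control[miss]
  ss$records <- r
  ss
}

ok_pairs <- function(pairs) pairs[pairs$status == "ok", , drop = FALSE]
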