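# Reverse-causation defenses: Steiger directionality filtering and
# bidirectional (disease -> protein) MR.

#' Effective sample size of a case-control study
#'
#' `4 / (1/n_case + 1/n_control)`, the standard equivalent-quantitative-trait
#' size used when comparing variance explained across designs.
#'
#' @param n_case,n_control case and control counts.
#' @return effective sample size.
#' @export
effective_n <- function(n_case, n_control) {
  stopifnot(all(n_case > 0), all(n_control > 0))
  4 / (1 / n_case + 1 / n_control)
}

#' Variance explained by a variant from its association z-score
#'
#' `r^2 = z^2 / (z^2 + n - 2)`, the exact identity between the squared
#' t-statistic and the squared correlation in simple regression. For
#' case-control traits pass the [effective_n].
#'
#' @param z association z-score(s) (`beta/se`).
#' @param n sample size(s), > 2.
#' @return variance explained, in `[0, 1)`.
#' @export
variance_explained <- function(z, n) {
  if (any(n <= 2)) stopf("variance_explained requires n > 2")
  z^2 / (z^2 + n - 2)
}

#' Steiger directionality test for a set of instruments
#'
#' Sums per-instrument variance explained in the exposure and in the outcome,
#' and compares the implied correlations `sqrt(r2)` with the
#' independent-samples Fisher-z test:
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp-3) + 1/(n_out-3))`,
#' two-sided. The causal direction is called correct when the instruments
#' explain more variance in the exposure than in the outcome; a small p-value
#' then indicates the asymmetry is unlikely under equality (no reverse
#' causality).
#'
#' @param pairs a [harmonize] result; only `ok` rows are used.
#' @param n_exp exposure sample size (> 3).
#' @param n_out outcome sample size (> 3); for case-control outcomes pass the
#'   [effective_n].
#' @return list of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `correct_direction`, `pvalue`, `n_snp`.
#' @export
steiger_filter <- function(pairs, n_exp, n_out) {
  okp <- ok_pairs(pairs)
  if (nrow(okp) == 0L) stopf("steiger_filter requires >= 1 ok pair")
  if (n_exp <= 3 || n_out <= 3) stopf("steiger_filter requires n > 3")
  r2_exp <- sum(variance_explained(okp$beta_exp / okp$se_exp, n_exp))
  r2_out <- sum(variance_explained(okp$beta_out / okp$se_out, n_out))
  r2_exp <- min(r2_exp, 1 - 1e-12)
  r2_out <- min(r2_out, 1 - 1e-12)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(list(r2_exposure = r2_exp, r2_outcome = r2_out,
                 correct_direction = r2_exp > r2_out,
                 pvalue = 2 * stats::pnorm(-abs(z)),
                 n_snp = nrow(okp)),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf(
    "<steiger_result> r2 exposure %.4g vs outcome %.4g: %s direction, p = %.3g\n",
    x$r2_exposure, x$r2_outcome,
    if (x$correct_direction) "correct" else "reversed", x$pvalue))
  invisible(x)
}

#' Bidirectional MR: disease as exposure, protein as outcome
#'
#' Selects genome-wide instruments from the disease GWAS under the same
#' criteria used for proteins (significance, clumping, F filter — but no cis
#' restriction), harmonizes them against the protein GWAS, and estimates the
#' disease -> protein effect. A p-value above 0.05 downstream is read as no
#' reverse causality.
#'
#' By default each candidate disease instrument is itself Steiger-filtered:
#' a variant explaining more variance in the protein than in the disease is
#' a protein instrument whose disease association is mediated, not a disease
#' instrument, and keeping it would mistake the forward effect for reverse
#' causation. Filtering requires per-record sample sizes on both traits and
#' is skipped (with all instruments kept) when they cannot be resolved.
#'
#' @param outcome_stats disease [summary_stats] (the instrument source).
#' @param exposure_stats protein [summary_stats] (here the outcome).
#' @param panel [ld_panel].
#' @param params [instrument_params] (cis restriction is not applied).
#' @param steiger_instruments drop candidate instruments whose variance
#'   explained in the protein exceeds that in the disease (default `TRUE`).
#' @param palindromic_eaf_limit see [harmonize].
#' @return An `mr_estimate`, or the string status `"lack_of_data"` when the
#'   disease GWAS yields no usable instrument.
#' @export
bidirectional_mr <- function(outcome_stats, exposure_stats, panel,
                             params = instrument_params(),
                             steiger_instruments = TRUE,
                             palindromic_eaf_limit = 0.42) {
  inst <- select_instruments(outcome_stats, region = NULL, panel = panel,
                             params = params)
  if (nrow(inst) == 0L) return("lack_of_data")
  pairs <- harmonize(outcome_stats, exposure_stats,
                     variant_ids = inst$variant_id,
                     palindromic_eaf_limit = palindromic_eaf_limit)
  if (steiger_instruments) {
    okp <- pairs$status == "ok"
    n_dis <- steiger_n(pairs$n_exp, outcome_stats)
    n_prot <- pairs$n_out
    can <- okp & !is.na(n_dis) & n_dis > 2 & !is.na(n_prot) & n_prot > 2
    if (any(can)) {
      r2_dis <- variance_explained(pairs$beta_exp[can] / pairs$se_exp[can],
                                   n_dis[can])
      r2_prot <- variance_explained(pairs$beta_out[can] / pairs$se_out[can],
                                    n_prot[can])
      drop_ids <- pairs$variant_id[can][r2_prot >= r2_dis]
      pairs <- pairs[!pairs$variant_id %in% drop_ids, , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0L) return("lack_of_data")
  est <- mr_estimate_pairs(pairs, exposure_id = outcome_stats$trait_id,
                           outcome_id = exposure_stats$trait_id)
  if (is.null(est)) return("lack_of_data")
  est
}

# effective size for the disease side of the reverse-direction Steiger
# check: case-control effective n when case counts are resolvable, else
# the total n carried on the record
steiger_n <- function(n_total, stats) {
  if (stats$trait_type == "case_control") {
    r <- resolve_n_soft(stats)$records
    nc <- if (!is.na(r$n_case[1])) r$n_case[1] else stats$default_n_case
    nco <- if (!is.na(r$n_control[1])) r$n_control[1] else
      stats$default_n_control
    if (!is.na(nc) && !is.na(nco))
      return(rep(effective_n(nc, nco), length(n_total)))
  }
  n_total
}

#' Combine Steiger and bidirectional MR into a direction verdict
#'
#' Passes when the Steiger test calls the correct direction with p < 0.05 and
#' the reverse (disease -> protein) MR is null at p > 0.05. A lack-of-data
#' reverse estimate leaves `passed = NA` (unknown).
#'
#' @param steiger a [steiger_filter] result.
#' @param reverse_mr an `mr_estimate` or `"lack_of_data"`.
#' @param alpha level for both checks (default 0.05).
#' @return list of class `direction_verdict` with `steiger`, `reverse_mr`,
#'   `passed`.
#' @export
direction_verdict <- function(steiger, reverse_mr, alpha = 0.05) {
  stopifnot(inherits(steiger, "steiger_result"))
  steiger_ok <- steiger$correct_direction && steiger$pvalue < alpha
  if (identical(reverse_mr, "lack_of_data")) {
    passed <- NA
  } else {
    passed <- steiger_ok && reverse_mr$pvalue > alpha
  }
  structure(list(steiger = steiger, reverse_mr = reverse_mr,
                 passed = passed),
            class = "direction_verdict")
}
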