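# Causal-effect estimation: Wald ratio, fixed-effect IVW, odds-ratio
# reporting, Bonferroni control, and the per-protein batch driver.

# 95% CI multiplier matching 2-decimal printed odds ratios
Z95 <- 1.959964

new_mr_estimate <- function(exposure_id, outcome_id, method, beta, se,
                            n_snp, snp_ids) {
  z <- beta / se
  pvalue <- 2 * stats::pnorm(-abs(z))
  structure(list(
    exposure_id = exposure_id, outcome_id = outcome_id, method = method,
    beta = beta, se = se, pvalue = pvalue,
    or_ = exp(beta),
    ci_low = exp(beta - Z95 * se), ci_high = exp(beta + Z95 * se),
    n_snp = n_snp, snp_ids = snp_ids), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<mr_estimate> %s -> %s  [%s, %d SNP%s]\n",
              x$exposure_id, x$outcome_id, x$method, x$n_snp,
              if (x$n_snp == 1) "" else "s"))
  cat(sprintf("  beta = %.*f (se %.*f), OR = %.*f (95%% CI %.*f-%.*f), p = %.3g\n",
              digits, x$beta, digits, x$se, digits, x$or_,
              digits, x$ci_low, digits, x$ci_high, x$pvalue))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  c(beta = object$beta, se = object$se, pvalue = object$pvalue)
}

#' Wald-ratio causal estimate from a single harmonized variant
#'
#' The ratio estimate `beta_out / beta_exp` with first-order delta-method
#' standard error `se_out / |beta_exp|`; two-sided p from the standard
#' normal.
#'
#' @param pair one row of a [harmonize] result with `status == "ok"`.
#' @return An `mr_estimate` (method `wald_ratio`, `n_snp = 1`).
#' @export
wald_ratio <- function(pair) {
  pair <- as.data.frame(pair)
  stopifnot(nrow(pair) == 1L)
  if (pair$status != "ok") stopf("wald_ratio requires an 'ok' pair")
  if (pair$beta_exp == 0) stopf("wald_ratio undefined for zero exposure beta")
  beta <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  new_mr_estimate(
    exposure_id = attr(pair, "exposure_id") %||% "exposure",
    outcome_id = attr(pair, "outcome_id") %||% "outcome",
    method = "wald_ratio", beta = beta, se = se, n_snp = 1L,
    snp_ids = pair$variant_id)
}

#' Fixed-effect inverse-variance weighted causal estimate
#'
#' Per-variant Wald ratios `b_j` with weights `w_j = 1/se_j^2`; the pooled
#' estimate is `sum(w_j b_j) / sum(w_j)` with standard error
#' `1/sqrt(sum(w_j))`. A multiplicative random-effects variant inflates the
#' standard error by the residual scale when it exceeds 1.
#'
#' @param pairs a [harmonize] result with at least two `ok` rows.
#' @param random_effects use the multiplicative random-effects standard
#'   error (default `FALSE`, fixed-effect).
#' @return An `mr_estimate` (method `ivw`).
#' @export
mr_ivw <- function(pairs, random_effects = FALSE) {
  okp <- ok_pairs(pairs)
  if (nrow(okp) < 2L)
    stopf("ivw requires >= 2 ok pairs; use wald_ratio for a single variant")
  if (any(okp$beta_exp == 0)) stopf("ivw undefined for zero exposure beta")
  b <- okp$beta_out / okp$beta_exp
  s <- okp$se_out / abs(okp$beta_exp)
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (random_effects) {
    phi <- sum(w * (b - beta)^2) / (nrow(okp) - 1)
    se <- se * sqrt(max(1, phi))
  }
  new_mr_estimate(
    exposure_id = attr(pairs, "exposure_id") %||% "exposure",
    outcome_id = attr(pairs, "outcome_id") %||% "outcome",
    method = "ivw", beta = beta, se = se, n_snp = nrow(okp),
    snp_ids = okp$variant_id)
}

#' Per-test Bonferroni threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (positive integer).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  stopifnot(is_scalar_number(alpha), alpha > 0, alpha < 1)
  if (!is_scalar_number(m) || m < 1 || m != round(m))
    stopf("m must be a positive integer")
  alpha / m
}

#' Estimate one protein's causal effect from its harmonized instruments
#'
#' Dispatches to [wald_ratio] for a single usable variant and [mr_ivw] for
#' two or more.
#'
#' @param pairs a [harmonize] result.
#' @param exposure_id,outcome_id labels carried into the estimate.
#' @return An `mr_estimate`, or `NULL` when no pair has status `ok`
#'   (lack of data).
#' @export
mr_estimate_pairs <- function(pairs, exposure_id = "exposure",
                              outcome_id = "outcome") {
  attr(pairs, "exposure_id") <- exposure_id
  attr(pairs, "outcome_id") <- outcome_id
  n_ok <- sum(pairs$status == "ok")
  if (n_ok == 0L) return(NULL)
  if (n_ok == 1L) {
    okp <- ok_pairs(pairs)
    attr(okp, "exposure_id") <- exposure_id
    attr(okp, "outcome_id") <- outcome_id
    wald_ratio(okp)
  } else {
    mr_ivw(pairs)
  }
}

#' Proteome-wide MR scan against one outcome
#'
#' Runs per-protein harmonization and Wald/IVW estimation, then flags
#' estimates significant at the Bonferroni threshold `alpha / m`, where `m`
#' is the number of proteins attempted (not the number with usable
#' instruments). Proteins with no usable instrument are reported with status
#' `lack_of_data`, never silently skipped.
#'
#' @param instrument_sets named list (one element per protein) of instrument
#'   data.frames from [select_instruments].
#' @param exposure_stats named list of protein [summary_stats] parallel to
#'   `instrument_sets`.
#' @param outcome outcome [summary_stats].
#' @param alpha family-wise level (default 0.05).
#' @param m Bonferroni denominator; defaults to the number of proteins
#'   attempted.
#' @param palindromic_eaf_limit see [harmonize].
#' @return list of class `mr_scan`: `results` data.frame (one row per
#'   protein: beta, se, pvalue, or_, ci, method, n_snp, status,
#'   significant), `estimates` (list of `mr_estimate`), `alpha`, `m`,
#'   `threshold`.
#' @export
mr_scan <- function(instrument_sets, exposure_stats, outcome, alpha = 0.05,
                    m = NULL, palindromic_eaf_limit = 0.42) {
  stopifnot(is.list(instrument_sets), !is.null(names(instrument_sets)))
  proteins <- names(instrument_sets)
  m <- m %||% length(proteins)
  threshold <- bonferroni_threshold(alpha, m)
  rows <- vector("list", length(proteins))
  ests <- stats::setNames(vector("list", length(proteins)), proteins)
  for (k in seq_along(proteins)) {
    p <- proteins[k]
    inst <- instrument_sets[[p]]
    est <- NULL
    if (!is.null(inst) && nrow(inst) > 0) {
      pairs <- harmonize(exposure_stats[[p]], outcome,
                         variant_ids = inst$variant_id,
                         palindromic_eaf_limit = palindromic_eaf_limit)
      est <- mr_estimate_pairs(pairs, exposure_id = p,
                               outcome_id = outcome$trait_id)
    }
    if (is.null(est)) {
      rows[[k]] <- data.frame(
        protein = p, outcome = outcome$trait_id, method = NA_character_,
        beta = NA_real_, se = NA_real_, pvalue = NA_real_, or_ = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, n_snp = 0L,
        status = "lack_of_data", significant = FALSE,
        stringsAsFactors = FALSE)
    } else {
      ests[[p]] <- est
      rows[[k]] <- data.frame(
        protein = p, outcome = outcome$trait_id, method = est$method,
        beta = est$beta, se = est$se, pvalue = est$pvalue, or_ = est$or_,
        ci_low = est$ci_low, ci_high = est$ci_high, n_snp = est$n_snp,
        status = "ok", significant = est$pvalue < threshold,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(results = do.call(rbind, rows), estimates = ests,
                 alpha = alpha, m = m, threshold = threshold),
            class = "mr_scan")
}

#' @export
print.mr_scan <- function(x, ...) {
  cat(sprintf("<mr_scan> %d protein(s), Bonferroni %g/%d = %.4g\n",
              nrow(x$results), x$alpha, x$m, x$threshold))
  cat(sprintf("  significant: %d; lack of data: %d\n",
              sum(x$results$significant),
              sum(x$results$status == "lack_of_data")))
  invisible(x)
}
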