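# Pleiotropy scanning against a local association catalog, phenome-wide MR
# with benefit/adverse classification, replication strategies, and the final
# evidence-integration verdict.

CATALOG_CLASSES <- c("target_disease", "risk_factor", "protein", "other")

#' Read a local variant-trait association catalog
#'
#' A desk-local stand-in for a phenotype-scanner lookup: every row records a
#' published association of a variant with a trait.
#'
#' @param path tab-separated table with columns `variant_id`, `trait_id`,
#'   `pvalue`, `trait_class` (one of `target_disease`, `risk_factor`,
#'   `protein`, `other`).
#' @return data.frame of class `annotation_catalog`.
#' @export
read_catalog <- function(path) {
  cat_df <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  annotation_catalog(cat_df)
}

#' Construct an association catalog from a data.frame
#' @param records data.frame with `variant_id`, `trait_id`, `pvalue`,
#'   `trait_class`.
#' @return data.frame of class `annotation_catalog`.
#' @export
annotation_catalog <- function(records) {
  need <- c("variant_id", "trait_id", "pvalue", "trait_class")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (!all(records$trait_class %in% CATALOG_CLASSES))
    stopf("trait_class must be one of: %s",
          paste(CATALOG_CLASSES, collapse = ", "))
  if (any(records$pvalue <= 0 | records$pvalue > 1))
    stopf("catalog p-values must lie in (0, 1]")
  class(records) <- c("annotation_catalog", "data.frame")
  records
}

#' Pleiotropy scan of instruments against the association catalog
#'
#' Drops instruments with a catalog association at `p < p_assoc` to the
#' target disease or a known risk factor. Additionally flags the protein as a
#' pleiotropy hub when its instruments associate (at the same threshold) with
#' at least `hub_min_proteins` distinct catalogued proteins; hub proteins are
#' excluded from the drug-target list (`phenoscan_pass = FALSE`) even though
#' their instruments are retained for estimation.
#'
#' @param instruments instrument data.frame (needs `variant_id`).
#' @param catalog [annotation_catalog].
#' @param p_assoc association threshold (default 5e-8, strict `<`).
#' @param hub_min_proteins distinct-protein count that makes a hub
#'   (default 2).
#' @return list: `instruments` (retained rows), `n_dropped`, `hub_flag`,
#'   `hub_proteins` (the distinct catalogued proteins hit),
#'   `phenoscan_pass` (`FALSE` when the protein is a hub).
#' @export
phenoscan_filter <- function(instruments, catalog, p_assoc = 5e-8,
                             hub_min_proteins = 2) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  hits <- catalog[catalog$variant_id %in% instruments$variant_id &
                    catalog$pvalue < p_assoc, , drop = FALSE]
  bad_ids <- unique(hits$variant_id[
    hits$trait_class %in% c("target_disease", "risk_factor")])
  retained <- instruments[!instruments$variant_id %in% bad_ids, ,
                          drop = FALSE]
  hub_proteins <- unique(hits$trait_id[hits$trait_class == "protein"])
  hub_flag <- length(hub_proteins) >= hub_min_proteins
  list(instruments = retained,
       n_dropped = nrow(instruments) - nrow(retained),
       hub_flag = hub_flag, hub_proteins = hub_proteins,
       phenoscan_pass = !hub_flag)
}

#' Phenome-wide MR screen of one protein across many outcomes
#'
#' Estimates the protein's effect on every outcome in the manifest, flags
#' results at the Bonferroni level `alpha / N` (N = outcomes attempted), and
#' classifies significant effects by direction consistency with the
#' protein's effect on the index disease: a concordant direction means a
#' drug against the protein would also `benefit` the screened disease; a
#' discordant one flags a potential `adverse` effect.
#'
#' @param instruments instrument data.frame for the protein.
#' @param exposure_stats protein [summary_stats].
#' @param outcomes named list of outcome [summary_stats].
#' @param index_beta the protein's causal beta on the index disease (direction
#'   reference).
#' @param alpha family-wise level (default 0.05).
#' @param palindromic_eaf_limit see [harmonize].
#' @return data.frame of class `phemr_records`: one row per outcome with
#'   estimate columns, `status`, `significant`, `classification` in
#'   `benefit`/`adverse`/`none`.
#' @export
phemr_screen <- function(instruments, exposure_stats, outcomes, index_beta,
                         alpha = 0.05, palindromic_eaf_limit = 0.42) {
  stopifnot(is.list(outcomes), length(outcomes) >= 1,
            !is.null(names(outcomes)), is_scalar_number(index_beta))
  n_out <- length(outcomes)
  threshold <- bonferroni_threshold(alpha, n_out)
  rows <- lapply(names(outcomes), function(oid) {
    est <- NULL
    if (nrow(instruments) > 0) {
      pairs <- harmonize(exposure_stats, outcomes[[oid]],
                         variant_ids = instruments$variant_id,
                         palindromic_eaf_limit = palindromic_eaf_limit)
      est <- mr_estimate_pairs(pairs, exposure_id = exposure_stats$trait_id,
                               outcome_id = oid)
    }
    if (is.null(est))
      return(data.frame(protein = exposure_stats$trait_id, outcome = oid,
                        beta = NA_real_, se = NA_real_, pvalue = NA_real_,
                        or_ = NA_real_, n_snp = 0L, status = "lack_of_data",
                        significant = FALSE, classification = "none",
                        stringsAsFactors = FALSE))
    sig <- est$pvalue < threshold
    classification <- if (!sig) "none" else
      if (sign(est$beta) == sign(index_beta)) "benefit" else "adverse"
    data.frame(protein = exposure_stats$trait_id, outcome = oid,
               beta = est$beta, se = est$se, pvalue = est$pvalue,
               or_ = est$or_, n_snp = est$n_snp, status = "ok",
               significant = sig, classification = classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  class(out) <- c("phemr_records", "data.frame")
  out
}

#' Replicate a discovery MR estimate in an independent pQTL cohort
#'
#' Two strategies: `same_variant` re-estimates with the discovery instrument
#' ids looked up in the replication exposure; `significant_variant`
#' re-selects instruments from the replication exposure under the discovery
#' criteria and then estimates. A replication passes when its p-value is
#' below the per-outcome threshold and its direction matches discovery.
#' Missing variants/instruments give `lack_of_data`; harmonization dropping
#' every pair gives `incompatible_alleles`.
#'
#' @param discovery_instruments discovery instrument data.frame.
#' @param discovery_beta discovery causal beta (direction reference).
#' @param replication_stats replication exposure [summary_stats].
#' @param outcome outcome [summary_stats].
#' @param strategy `"same_variant"` or `"significant_variant"`.
#' @param threshold per-outcome replication p threshold (e.g. 0.05 divided by
#'   the outcome's discovery hit count).
#' @param region [cis_region] (used by `significant_variant` re-selection).
#' @param panel [ld_panel] (idem).
#' @param params [instrument_params] (idem).
#' @param palindromic_eaf_limit see [harmonize].
#' @return list of class `replication_result`: `strategy`, `status`
#'   (`passed`, `failed`, `lack_of_data`, `incompatible_alleles`),
#'   `estimate` (`mr_estimate` or `NULL`), `threshold`.
#' @export
replicate_estimate <- function(discovery_instruments, discovery_beta,
                               replication_stats, outcome,
                               strategy = c("same_variant",
                                            "significant_variant"),
                               threshold, region = NULL, panel = NULL,
                               params = instrument_params(),
                               palindromic_eaf_limit = 0.42) {
  strategy <- match.arg(strategy)
  stopifnot(is_scalar_number(threshold), threshold > 0, threshold < 1)
  done <- function(status, estimate = NULL)
    structure(list(strategy = strategy, status = status,
                   estimate = estimate, threshold = threshold),
              class = "replication_result")

  if (strategy == "same_variant") {
    ids <- discovery_instruments$variant_id
    present <- ids %in% replication_stats$records$variant_id
    if (length(ids) == 0L || !any(present)) return(done("lack_of_data"))
    ids <- ids[present]
  } else {
    if (is.null(panel)) stopf("significant_variant strategy needs an LD panel")
    inst <- select_instruments(replication_stats, region = region,
                               panel = panel, params = params)
    if (nrow(inst) == 0L) return(done("lack_of_data"))
    ids <- inst$variant_id
  }
  pairs <- harmonize(replication_stats, outcome, variant_ids = ids,
                     palindromic_eaf_limit = palindromic_eaf_limit)
  if (all(pairs$status != "ok")) {
    if (any(pairs$status %in% c("dropped_incompatible",
                                "dropped_palindromic")))
      return(done("incompatible_alleles"))
    return(done("lack_of_data"))
  }
  est <- mr_estimate_pairs(pairs, exposure_id = replication_stats$trait_id,
                           outcome_id = outcome$trait_id)
  passed <- est$pvalue < threshold && sign(est$beta) == sign(discovery_beta)
  done(if (passed) "passed" else "failed", est)
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("<replication_result> %s: %s (threshold %.4g)\n",
              x$strategy, x$status, x$threshold))
  if (!is.null(x$estimate))
    cat(sprintf("  beta = %.4g, p = %.3g\n", x$estimate$beta,
                x$estimate$pvalue))
  invisible(x)
}

EVIDENCE_FLAGS <- c("discovery_significant", "steiger_pass",
                    "bidirectional_pass", "phenoscan_pass", "coloc_pass",
                    "replication_significant_pass", "replication_same_pass")

#' Conjoin per-target filter flags into the final evidence verdict
#'
#' A protein-outcome pair is called a potential drug target (`YES`) only when
#' every filter passes affirmatively: discovery significance, Steiger
#' direction, bidirectional-MR null, pleiotropy scan, colocalization, and
#' both replication strategies. A missing (unknown / lack-of-data) flag
#' vetoes the verdict.
#'
#' @param flags data.frame with `protein`, `outcome` and logical columns
#'   `discovery_significant`, `steiger_pass`, `bidirectional_pass`,
#'   `phenoscan_pass`, `coloc_pass`, `replication_significant_pass`,
#'   `replication_same_pass` (NA = unknown).
#' @return the input with a `verdict` column (`"YES"`/`"NO"`), classed
#'   `evidence_table`.
#' @export
evidence_summary <- function(flags) {
  stopifnot(is.data.frame(flags),
            all(c("protein", "outcome") %in% names(flags)),
            all(EVIDENCE_FLAGS %in% names(flags)))
  fl <- as.matrix(flags[EVIDENCE_FLAGS])
  storage.mode(fl) <- "logical"
  all_pass <- apply(fl, 1, function(v) all(!is.na(v)) && all(v))
  flags$verdict <- ifelse(all_pass, "YES", "NO")
  class(flags) <- c("evidence_table", "data.frame")
  flags
}

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("<evidence_table> %d row(s), %d YES verdict(s)\n",
              nrow(x), sum(x$verdict == "YES")))
  print.data.frame(x[, c("protein", "outcome", "verdict")])
  invisible(x)
}

#' Read a published-evidence digest table
#'
#' Loads a tab-separated digest of per-target printed results (MR p-values,
#' PPH4 posteriors and pass/fail annotations for every filter) so the
#' evidence conjunction and threshold rules can be replayed on reported
#' numbers without the restricted source data.
#'
#' @param path TSV with columns `outcome, protein, snp, or_, ci_low, ci_high,
#'   pvalue, steiger_pvalue, steiger_flag, bidir_pvalue, bidir_flag,
#'   phenoscan_flag, pph4, coloc_flag, rep_sig_pvalue, rep_sig_flag,
#'   rep_same_pvalue, rep_same_flag` (flags are `Passed`, `NO`,
#'   `Lack of data`, or `*` for incompatible alleles; empty = not printed).
#' @return data.frame.
#' @export
read_evidence_digest <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    quote = "\"")
}

flag_to_logical <- function(flag) {
  out <- rep(NA, length(flag))
  out[!is.na(flag) & flag == "Passed"] <- TRUE
  out[!is.na(flag) & flag == "NO"] <- FALSE
  out  # "Lack of data", "*", or missing stay NA (unknown)
}

#' Replay the evidence conjunction on a published-results digest
#'
#' Recomputes, from printed values: discovery significance at
#' `alpha / m_discovery`, the colocalization call at `pph4 > coloc_threshold`,
#' and the conjunction of all printed filter flags.
#'
#' @param digest a [read_evidence_digest] table.
#' @param alpha family-wise level (default 0.05).
#' @param m_discovery discovery Bonferroni denominator (e.g. number of
#'   proteins screened).
#' @param coloc_threshold PPH4 cutoff (default 0.7, strict `>`).
#' @param coloc_from `"flag"` (default) takes the printed colocalization
#'   annotation as the conjunction input; `"pph4"` re-derives it from the
#'   printed posterior and the threshold.
#' @return [evidence_summary] table with additional columns
#'   `discovery_significant` and `coloc_pass_pph4`.
#' @export
evidence_replay <- function(digest, alpha = 0.05, m_discovery,
                            coloc_threshold = 0.7,
                            coloc_from = c("flag", "pph4")) {
  coloc_from <- match.arg(coloc_from)
  thr <- bonferroni_threshold(alpha, m_discovery)
  coloc_pph4 <- !is.na(digest$pph4) & digest$pph4 > coloc_threshold
  coloc_pph4[is.na(digest$pph4)] <- NA
  flags <- data.frame(
    protein = digest$protein, outcome = digest$outcome,
    discovery_significant = digest$pvalue < thr,
    steiger_pass = flag_to_logical(digest$steiger_flag),
    bidirectional_pass = flag_to_logical(digest$bidir_flag),
    phenoscan_pass = flag_to_logical(digest$phenoscan_flag),
    coloc_pass = if (coloc_from == "flag")
      flag_to_logical(digest$coloc_flag) else coloc_pph4,
    replication_significant_pass = flag_to_logical(digest$rep_sig_flag),
    replication_same_pass = flag_to_logical(digest$rep_same_flag),
    stringsAsFactors = FALSE)
  out <- evidence_summary(flags)
  out$coloc_pass_pph4 <- coloc_pph4
  out
}
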