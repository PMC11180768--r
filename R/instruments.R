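# Cis-instrument selection: significance filter, greedy LD clumping,
# weak-instrument (F-statistic) filter, cis-window restriction.

#' Cis region around a gene anchor
#'
#' @param gene gene symbol.
#' @param chrom chromosome label.
#' @param anchor_pos base-pair anchor (typically the transcription start
#'   site), 1-based.
#' @param cis_radius half-width of the cis window in base pairs (default
#'   1 Mb). The window is the closed interval
#'   `[anchor_pos - cis_radius, anchor_pos + cis_radius]`, floored at 1.
#' @return list of class `cis_region` with `gene`, `chrom`, `start`, `end`.
#' @export
cis_region <- function(gene, chrom, anchor_pos, cis_radius = 1e6) {
  stopifnot(is_scalar_number(anchor_pos), anchor_pos >= 1,
            is_scalar_number(cis_radius), cis_radius >= 0)
  structure(list(gene = as.character(gene), chrom = as.character(chrom),
                 start = max(1, anchor_pos - cis_radius),
                 end = anchor_pos + cis_radius),
            class = "cis_region")
}

#' Instrument-strength F-statistic
#'
#' The squared z-score `(beta/se)^2`, the standard approximation to the
#' first-stage F for a single variant. Values below 10 conventionally flag
#' weak instruments.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), all > 0.
#' @return numeric vector of F values.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0))
    stopf("f_statistic requires se > 0")
  (beta / se)^2
}

#' Greedy LD clumping
#'
#' Iteratively takes the smallest-p unclaimed candidate as an index variant
#' and discards every other unclaimed candidate on the same chromosome within
#' `window_kb` of it whose r^2 with the index exceeds `r2_max`. P-value ties
#' are broken lexicographically by variant id for reproducibility.
#'
#' @param candidates data.frame with `variant_id`, `chrom`, `pos`, `pvalue`
#'   (e.g. the records of a [summary_stats]).
#' @param panel [ld_panel]; candidates absent from the panel are dropped with
#'   a logged count.
#' @param r2_max r^2 threshold above which a neighbour is discarded
#'   (default 0.001).
#' @param window_kb clumping window in kilobases (default 10000).
#' @param verbose log the dropped-candidate count.
#' @return the retained index variants, sorted by p-value ascending (ties by
#'   variant id).
#' @export
greedy_clump <- function(candidates, panel, r2_max = 0.001,
                         window_kb = 10000, verbose = FALSE) {
  stopifnot(is.data.frame(candidates),
            all(c("variant_id", "chrom", "pos", "pvalue") %in%
                  names(candidates)))
  in_panel <- candidates$variant_id %in% panel_variants(panel)
  if (any(!in_panel))
    log_kv("clump", dropped_absent_from_panel = sum(!in_panel),
           verbose = verbose)
  cand <- candidates[in_panel, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$pvalue, cand$variant_id), , drop = FALSE]
  window_bp <- window_kb * 1000
  unclaimed <- rep(TRUE, nrow(cand))
  keep <- logical(nrow(cand))
  while (any(unclaimed)) {
    idx <- which(unclaimed)[1]          # smallest p among unclaimed
    keep[idx] <- TRUE
    unclaimed[idx] <- FALSE
    near <- which(unclaimed &
                    cand$chrom == cand$chrom[idx] &
                    abs(cand$pos - cand$pos[idx]) <= window_bp)
    if (length(near) > 0) {
      r2 <- as.vector(ld_r2(panel, cand$variant_id[idx],
                            cand$variant_id[near]))
      unclaimed[near[r2 > r2_max]] <- FALSE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-selection thresholds
#'
#' @param p_threshold genome-wide significance cut-off; variants with
#'   `pvalue < p_threshold` qualify (p equal to the threshold is excluded).
#' @param r2_max,window_kb clumping parameters (see [greedy_clump]).
#' @param f_min minimum F-statistic; variants with `F < f_min` are excluded
#'   (F equal to the threshold is retained).
#' @param cis_radius cis-window half-width in base pairs.
#' @return list of class `instrument_params`.
#' @export
instrument_params <- function(p_threshold = 5e-8, r2_max = 0.001,
                              window_kb = 10000, f_min = 10,
                              cis_radius = 1e6) {
  stopifnot(p_threshold > 0, p_threshold < 1, r2_max >= 0, r2_max <= 1,
            window_kb > 0, f_min >= 0, cis_radius >= 0)
  structure(list(p_threshold = p_threshold, r2_max = r2_max,
                 window_kb = window_kb, f_min = f_min,
                 cis_radius = cis_radius),
            class = "instrument_params")
}

#' Select cis instruments for one protein
#'
#' Applies, in order: cis-window restriction, genome-wide significance filter,
#' greedy LD clumping, weak-instrument F filter. An empty result is legal.
#'
#' @param protein_stats [summary_stats] for the protein GWAS.
#' @param region [cis_region] for the encoding gene; `NULL` skips the cis
#'   restriction (used when selecting genome-wide instruments from a disease
#'   GWAS for bidirectional MR).
#' @param panel [ld_panel].
#' @param params [instrument_params].
#' @param verbose log stage counts.
#' @return data.frame of instruments: the variant record columns plus
#'   `f_stat`, `is_cis`, `clump_index`; sorted by p ascending. Zero rows when
#'   nothing survives (a warning is logged when the region's chromosome is
#'   absent from the stats).
#' @export
select_instruments <- function(protein_stats, region, panel,
                               params = instrument_params(),
                               verbose = FALSE) {
  stopifnot(inherits(protein_stats, "summary_stats"),
            inherits(params, "instrument_params"))
  r <- resolve_n_soft(protein_stats)$records
  empty <- function() {
    out <- r[0, , drop = FALSE]
    out$f_stat <- numeric(0); out$is_cis <- logical(0)
    out$clump_index <- logical(0)
    out
  }
  if (!is.null(region)) {
    stopifnot(inherits(region, "cis_region"))
    if (!any(r$chrom == region$chrom)) {
      warning(sprintf("chromosome %s absent from trait '%s'; no instruments",
                      region$chrom, protein_stats$trait_id), call. = FALSE)
      return(empty())
    }
    r <- r[r$chrom == region$chrom & r$pos >= region$start &
             r$pos <= region$end, , drop = FALSE]
  }
  log_kv("instruments", trait = protein_stats$trait_id, cis = nrow(r),
         verbose = verbose)
  r <- r[r$pvalue < params$p_threshold, , drop = FALSE]
  if (nrow(r) == 0L) return(empty())
  r <- greedy_clump(r, panel, r2_max = params$r2_max,
                    window_kb = params$window_kb, verbose = verbose)
  if (nrow(r) == 0L) return(empty())
  r$f_stat <- f_statistic(r$beta, r$se)
  r <- r[r$f_stat >= params$f_min, , drop = FALSE]  # F < f_min excluded
  r$is_cis <- rep(!is.null(region), nrow(r))
  r$clump_index <- rep(TRUE, nrow(r))
  rownames(r) <- NULL
  log_kv("instruments", trait = protein_stats$trait_id, selected = nrow(r),
         verbose = verbose)
  r
}

#' Read a protein annotation table
#'
#' @param path tab-separated table with columns `gene`, `chrom`,
#'   `anchor_pos` (gene anchor, e.g. TSS).
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "anchor_pos")
  if (!all(need %in% names(g)))
    stopf("gene table %s must have columns: %s", path,
          paste(need, collapse = ", "))
  g$chrom <- as.character(g$chrom)
  g
}
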