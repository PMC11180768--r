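# End-to-end orchestration: instrument selection -> MR scan -> direction
# tests -> pleiotropy scan -> colocalization -> replication -> Phe-MR ->
# evidence conjunction. Every protein appears exactly once in the final
# table with a status, wherever it dropped out.

PIPELINE_THRESHOLD_DEFAULTS <- list(
  p_instrument = 5e-8, r2_max = 0.001, window_kb = 10000, f_min = 10,
  cis_radius = 1e6, alpha = 0.05, steiger_alpha = 0.05,
  p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
  prior_sd_quant = 0.15, prior_sd_cc = 0.2,
  pph4_threshold = 0.7, palindromic_eaf_limit = 0.42,
  phenoscan_p = 5e-8, hub_min_proteins = 2)

#' Assemble and validate a pipeline configuration
#'
#' @param proteins data.frame with `gene`, `chrom`, `anchor_pos` (one row
#'   per protein).
#' @param exposure named list of protein [summary_stats] (names = genes).
#' @param outcome index-disease [summary_stats].
#' @param panel [ld_panel].
#' @param replication optional named list of replication-cohort
#'   [summary_stats] per protein.
#' @param catalog optional [annotation_catalog] for the pleiotropy scan.
#' @param phemr_outcomes optional named list of outcome [summary_stats] for
#'   the phenome-wide screen.
#' @param thresholds named list overriding any of: `p_instrument`, `r2_max`,
#'   `window_kb`, `f_min`, `cis_radius`, `alpha`, `steiger_alpha`, `p1`,
#'   `p2`, `p12`, `prior_sd_quant`, `prior_sd_cc`, `pph4_threshold`,
#'   `palindromic_eaf_limit`, `phenoscan_p`, `hub_min_proteins`. Unknown
#'   keys are rejected.
#' @param seed integer seed applied before any stochastic stage.
#' @param outdir optional directory for per-stage TSV artifacts.
#' @param verbose emit structured `key=value` stage logs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, exposure, outcome, panel,
                            replication = NULL, catalog = NULL,
                            phemr_outcomes = NULL, thresholds = list(),
                            seed = 1L, outdir = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(proteins),
            all(c("gene", "chrom", "anchor_pos") %in% names(proteins)),
            is.list(exposure), !is.null(names(exposure)),
            inherits(outcome, "summary_stats"), inherits(panel, "ld_panel"))
  unknown <- setdiff(names(thresholds), names(PIPELINE_THRESHOLD_DEFAULTS))
  if (length(unknown) > 0)
    stopf("unknown threshold key(s): %s", paste(unknown, collapse = ", "))
  thr <- utils::modifyList(PIPELINE_THRESHOLD_DEFAULTS, thresholds)
  with(thr, {
    stopifnot(p_instrument > 0, p_instrument < 1, r2_max >= 0, r2_max <= 1,
              window_kb > 0, f_min >= 0, cis_radius >= 0,
              alpha > 0, alpha < 1, pph4_threshold > 0, pph4_threshold < 1,
              palindromic_eaf_limit > 0, palindromic_eaf_limit < 0.5)
  })
  missing_exp <- setdiff(proteins$gene, names(exposure))
  if (length(missing_exp) > 0)
    stopf("no exposure summary statistics for: %s",
          paste(missing_exp, collapse = ", "))
  structure(list(proteins = proteins, exposure = exposure,
                 outcome = outcome, panel = panel,
                 replication = replication, catalog = catalog,
                 phemr_outcomes = phemr_outcomes, thresholds = thr,
                 seed = as.integer(seed), outdir = outdir,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' File-path fields (`proteins`, `exposure` mapping gene -> path, `outcome`,
#' `panel` with `haplotypes`/`sites` or `r2`, optional `replication`,
#' `catalog`, `phemr_outcomes` mapping id -> path) are loaded into objects;
#' `thresholds`, `seed`, `outdir` pass through. Per-trait sample sizes come
#' from `outcome_n_case` / `outcome_n_control` / `exposure_n` keys. Unknown
#' top-level keys are rejected.
#'
#' @param path YAML file path; relative data paths resolve against its
#'   directory.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("proteins", "exposure", "outcome", "panel", "replication",
             "catalog", "phemr_outcomes", "thresholds", "seed", "outdir",
             "exposure_n", "outcome_n_case", "outcome_n_control",
             "dialect", "verbose")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  base <- dirname(normalizePath(path))
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  dialect <- if (!is.null(cfg$dialect)) unlist(cfg$dialect) else NULL
  read_exp <- function(p, id)
    read_sumstats(rel(p), dialect = dialect, trait_id = id,
                  trait_type = "quantitative",
                  default_n = cfg$exposure_n %||% NA_real_, verbose = FALSE)
  exposure <- stats::setNames(
    lapply(names(cfg$exposure), function(g) read_exp(cfg$exposure[[g]], g)),
    names(cfg$exposure))
  outcome <- read_sumstats(rel(cfg$outcome), dialect = dialect,
                           trait_id = "outcome",
                           trait_type = "case_control",
                           default_n_case = cfg$outcome_n_case %||% NA_real_,
                           default_n_control = cfg$outcome_n_control %||%
                             NA_real_, verbose = FALSE)
  panel <- if (!is.null(cfg$panel$haplotypes))
    read_ld_panel(haplotypes_path = rel(cfg$panel$haplotypes),
                  sites_path = rel(cfg$panel$sites))
  else read_ld_panel(r2_path = rel(cfg$panel$r2),
                     sites_path = if (is.null(cfg$panel$sites)) NULL else
                       rel(cfg$panel$sites))
  replication <- if (!is.null(cfg$replication))
    stats::setNames(lapply(names(cfg$replication), function(g)
      read_exp(cfg$replication[[g]], paste0(g, "_replication"))),
      names(cfg$replication))
  catalog <- if (!is.null(cfg$catalog)) read_catalog(rel(cfg$catalog))
  phemr <- if (!is.null(cfg$phemr_outcomes))
    stats::setNames(lapply(names(cfg$phemr_outcomes), function(id)
      read_sumstats(rel(cfg$phemr_outcomes[[id]]), dialect = dialect,
                    trait_id = id, trait_type = "case_control",
                    verbose = FALSE)),
      names(cfg$phemr_outcomes))
  pipeline_config(
    proteins = read_gene_table(rel(cfg$proteins)), exposure = exposure,
    outcome = outcome, panel = panel, replication = replication,
    catalog = catalog, phemr_outcomes = phemr,
    thresholds = cfg$thresholds %||% list(), seed = cfg$seed %||% 1L,
    outdir = cfg$outdir, verbose = isTRUE(cfg$verbose))
}

write_stage <- function(df, outdir, name) {
  if (is.null(outdir) || is.null(df) || nrow(df) == 0) return(invisible())
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full drug-target MR pipeline
#'
#' Executes instrument selection, the MR scan (Bonferroni over the proteins
#' attempted), Steiger and bidirectional direction tests, the pleiotropy
#' scan, colocalization, both replication strategies (per-outcome threshold
#' = alpha / number of discovery hits), the phenome-wide screen, and the
#' evidence conjunction. Proteins that drop out at any stage carry explicit
#' statuses through to the final table.
#'
#' @param config [pipeline_config].
#' @return list of class `mr_pipeline`: `evidence` ([evidence_summary]
#'   table), `mr` (the [mr_scan]), `instruments`, `direction`, `coloc`,
#'   `replication`, `phemr` data.frames, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  verbose <- config$verbose
  set.seed(config$seed)
  params <- instrument_params(p_threshold = thr$p_instrument,
                              r2_max = thr$r2_max,
                              window_kb = thr$window_kb, f_min = thr$f_min,
                              cis_radius = thr$cis_radius)
  genes <- config$proteins$gene
  if (length(genes) == 0L) {
    empty <- evidence_summary(data.frame(
      protein = character(0), outcome = character(0),
      discovery_significant = logical(0), steiger_pass = logical(0),
      bidirectional_pass = logical(0), phenoscan_pass = logical(0),
      coloc_pass = logical(0), replication_significant_pass = logical(0),
      replication_same_pass = logical(0)))
    return(structure(list(evidence = empty, mr = NULL, instruments = NULL,
                          direction = NULL, coloc = NULL,
                          replication = NULL, phemr = NULL,
                          config = config), class = "mr_pipeline"))
  }

  # stage 1: cis instruments per protein
  regions <- stats::setNames(lapply(seq_along(genes), function(i)
    cis_region(genes[i], config$proteins$chrom[i],
               config$proteins$anchor_pos[i],
               cis_radius = thr$cis_radius)), genes)
  instruments <- stats::setNames(lapply(genes, function(g)
    select_instruments(config$exposure[[g]], regions[[g]], config$panel,
                       params = params, verbose = verbose)), genes)
  inst_df <- do.call(rbind, lapply(genes, function(g) {
    x <- instruments[[g]]
    if (nrow(x) == 0) return(NULL)
    cbind(protein = g, x)
  }))
  log_kv("instruments", proteins = length(genes),
         with_instruments = sum(vapply(instruments, nrow, 0L) > 0),
         verbose = verbose)

  # stage 2: discovery MR scan (m = proteins attempted)
  scan <- mr_scan(instruments, config$exposure, config$outcome,
                  alpha = thr$alpha,
                  palindromic_eaf_limit = thr$palindromic_eaf_limit)
  log_kv("mr", tested = nrow(scan$results),
         significant = sum(scan$results$significant), verbose = verbose)
  n_hits <- max(1L, sum(scan$results$significant))
  rep_threshold <- bonferroni_threshold(thr$alpha, n_hits)

  outcome_res <- resolve_n(config$outcome)
  n_out_eff <- effective_n(outcome_res$records$n_case[1],
                           outcome_res$records$n_control[1])

  direction_rows <- list(); coloc_rows <- list(); rep_rows <- list()
  phemr_rows <- list(); flag_rows <- list()

  for (g in genes) {
    row <- scan$results[scan$results$protein == g, ]
    flags <- list(protein = g, outcome = config$outcome$trait_id,
                  discovery_significant = NA, steiger_pass = NA,
                  bidirectional_pass = NA, phenoscan_pass = NA,
                  coloc_pass = NA, replication_significant_pass = NA,
                  replication_same_pass = NA)
    if (row$status == "lack_of_data") {
      flag_rows[[g]] <- as.data.frame(flags, stringsAsFactors = FALSE)
      next
    }
    flags$discovery_significant <- row$significant
    if (!row$significant) {
      # short-circuit: downstream filters run only for discovery hits
      flag_rows[[g]] <- as.data.frame(flags, stringsAsFactors = FALSE)
      next
    }
    inst <- instruments[[g]]
    exposure <- config$exposure[[g]]
    pairs <- harmonize(exposure, config$outcome,
                       variant_ids = inst$variant_id,
                       palindromic_eaf_limit = thr$palindromic_eaf_limit)
    n_exp <- exposure$default_n %||% mean(pairs$n_exp, na.rm = TRUE)
    if (is.na(n_exp)) n_exp <- mean(pairs$n_exp, na.rm = TRUE)

    # stage 3: direction tests
    st <- steiger_filter(pairs, n_exp = n_exp, n_out = n_out_eff)
    protein_outcome_stats <- config$replication[[g]] %||% exposure
    rev_est <- bidirectional_mr(config$outcome, protein_outcome_stats,
                                config$panel, params = params,
                                palindromic_eaf_limit =
                                  thr$palindromic_eaf_limit)
    verdict <- direction_verdict(st, rev_est, alpha = thr$steiger_alpha)
    flags$steiger_pass <- st$correct_direction &&
      st$pvalue < thr$steiger_alpha
    flags$bidirectional_pass <- if (identical(rev_est, "lack_of_data")) NA
      else rev_est$pvalue > thr$steiger_alpha
    direction_rows[[g]] <- data.frame(
      protein = g, steiger_p = st$pvalue,
      steiger_correct = st$correct_direction,
      reverse_beta = if (identical(rev_est, "lack_of_data")) NA_real_ else
        rev_est$beta,
      reverse_p = if (identical(rev_est, "lack_of_data")) NA_real_ else
        rev_est$pvalue,
      passed = verdict$passed, stringsAsFactors = FALSE)

    # stage 4: pleiotropy scan
    if (!is.null(config$catalog)) {
      ps <- phenoscan_filter(inst, config$catalog,
                             p_assoc = thr$phenoscan_p,
                             hub_min_proteins = thr$hub_min_proteins)
      flags$phenoscan_pass <- ps$phenoscan_pass &&
        nrow(ps$instruments) > 0
    } else flags$phenoscan_pass <- TRUE

    # stage 5: colocalization over the cis window
    reg <- regions[[g]]
    er <- exposure$records
    er <- er[er$chrom == reg$chrom & er$pos >= reg$start &
               er$pos <= reg$end, ]
    cl <- coloc_abf(er, config$outcome$records,
                    priors = coloc_priors(thr$p1, thr$p2, thr$p12),
                    sd1 = thr$prior_sd_quant, sd2 = thr$prior_sd_cc)
    flags$coloc_pass <- cl$pph4 > thr$pph4_threshold
    coloc_rows[[g]] <- data.frame(
      protein = g, n_snps = cl$n_snps, pph0 = cl$pph0, pph1 = cl$pph1,
      pph2 = cl$pph2, pph3 = cl$pph3, pph4 = cl$pph4,
      call = coloc_call(cl, thr$pph4_threshold), stringsAsFactors = FALSE)

    # stage 6: replication, both strategies
    if (!is.null(config$replication[[g]])) {
      for (strat in c("significant_variant", "same_variant")) {
        rr <- replicate_estimate(
          inst, discovery_beta = row$beta,
          replication_stats = config$replication[[g]],
          outcome = config$outcome, strategy = strat,
          threshold = rep_threshold, region = regions[[g]],
          panel = config$panel, params = params,
          palindromic_eaf_limit = thr$palindromic_eaf_limit)
        fl <- if (rr$status == "passed") TRUE else
          if (rr$status == "failed") FALSE else NA
        if (strat == "significant_variant")
          flags$replication_significant_pass <- fl
        else flags$replication_same_pass <- fl
        rep_rows[[paste(g, strat)]] <- data.frame(
          protein = g, strategy = strat, status = rr$status,
          beta = if (is.null(rr$estimate)) NA_real_ else rr$estimate$beta,
          pvalue = if (is.null(rr$estimate)) NA_real_ else
            rr$estimate$pvalue,
          threshold = rep_threshold, stringsAsFactors = FALSE)
      }
    }

    # stage 7: phenome-wide screen
    if (!is.null(config$phemr_outcomes)) {
      ph <- phemr_screen(inst, exposure, config$phemr_outcomes,
                         index_beta = row$beta, alpha = thr$alpha,
                         palindromic_eaf_limit = thr$palindromic_eaf_limit)
      phemr_rows[[g]] <- as.data.frame(ph)
    }
    flag_rows[[g]] <- as.data.frame(flags, stringsAsFactors = FALSE)
  }

  evidence <- evidence_summary(do.call(rbind, flag_rows))
  log_kv("evidence", rows = nrow(evidence),
         yes = sum(evidence$verdict == "YES"), verbose = verbose)

  direction <- if (length(direction_rows)) do.call(rbind, direction_rows)
  coloc <- if (length(coloc_rows)) do.call(rbind, coloc_rows)
  replication <- if (length(rep_rows)) do.call(rbind, rep_rows)
  phemr <- if (length(phemr_rows)) do.call(rbind, phemr_rows)

  write_stage(inst_df, config$outdir, "instruments")
  write_stage(scan$results, config$outdir, "mr")
  write_stage(direction, config$outdir, "direction")
  write_stage(coloc, config$outdir, "coloc")
  write_stage(replication, config$outdir, "replication")
  write_stage(phemr, config$outdir, "phemr")
  write_stage(as.data.frame(evidence), config$outdir, "evidence")

  structure(list(evidence = evidence, mr = scan, instruments = inst_df,
                 direction = direction, coloc = coloc,
                 replication = replication, phemr = phemr,
                 config = config),
            class = "mr_pipeline")
}

#' @export
print.mr_pipeline <- function(x, ...) {
  cat(sprintf("<mr_pipeline> %d protein(s) -> %d YES verdict(s)\n",
              nrow(x$evidence), sum(x$evidence$verdict == "YES")))
  invisible(x)
}

#' @export
summary.mr_pipeline <- function(object, ...) {
  cat("Drug-target MR pipeline summary\n")
  if (!is.null(object$mr)) print(object$mr)
  print(object$evidence)
  invisible(object)
}
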