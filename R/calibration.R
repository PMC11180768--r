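# Replicate-level calibration drivers and a multi-protein synthetic study
# builder. These are what the validation suite (and any user wanting to
# check operating characteristics at their own scale) runs.

#' Run seeded MR replicates of one scenario and score each against truth
#'
#' For every replicate: simulate a panel and a paired exposure/outcome
#' dataset, select cis instruments, harmonize, estimate the causal effect
#' (Wald/IVW), and run the Steiger test. The RNG is seeded once at entry, so
#' the whole sequence is reproducible from `seed`.
#'
#' @param hypothesis scenario hypothesis (see [sim_scenario]).
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param scenario_args named list of overrides passed to [sim_scenario].
#' @param params [instrument_params].
#' @return data.frame, one row per replicate: `n_instruments`, `beta`, `se`,
#'   `pvalue` (NA when no instrument survived), `steiger_correct`,
#'   `steiger_p`.
#' @export
run_mr_replicates <- function(hypothesis, n_reps, seed = 1L,
                              scenario_args = list(),
                              params = instrument_params()) {
  set.seed(seed)
  sc <- do.call(sim_scenario, c(list(hypothesis = hypothesis),
                                scenario_args))
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    panel <- simulate_panel(sc$n_hap, sc$n_variants, sc$ld_decay,
                            span = sc$cis_span)
    sim <- simulate_two_trait_gwas(panel, sc)
    region <- cis_region("sim", "1",
                         panel$sites$pos[sc$causal_exposure],
                         cis_radius = params$cis_radius)
    inst <- select_instruments(sim$exposure, region, panel, params = params)
    if (nrow(inst) == 0L) {
      rows[[i]] <- data.frame(n_instruments = 0L, beta = NA_real_,
                              se = NA_real_, pvalue = NA_real_,
                              steiger_correct = NA, steiger_p = NA_real_)
      next
    }
    pairs <- harmonize(sim$exposure, sim$outcome,
                       variant_ids = inst$variant_id)
    est <- mr_estimate_pairs(pairs)
    orec <- sim$outcome$records
    st <- steiger_filter(pairs, n_exp = sc$n_exposure,
                         n_out = effective_n(orec$n_case[1],
                                             orec$n_control[1]))
    rows[[i]] <- data.frame(
      n_instruments = nrow(inst),
      beta = if (is.null(est)) NA_real_ else est$beta,
      se = if (is.null(est)) NA_real_ else est$se,
      pvalue = if (is.null(est)) NA_real_ else est$pvalue,
      steiger_correct = st$correct_direction, steiger_p = st$pvalue)
  }
  do.call(rbind, rows)
}

#' Run seeded colocalization replicates of one scenario
#'
#' Each replicate simulates a region under the given hypothesis and runs
#' [coloc_abf] on the full region for both traits.
#'
#' @inheritParams run_mr_replicates
#' @param priors [coloc_priors].
#' @return data.frame with `pph0` .. `pph4` and `n_snps` per replicate.
#' @export
run_coloc_replicates <- function(hypothesis, n_reps, seed = 1L,
                                 scenario_args = list(),
                                 priors = coloc_priors()) {
  set.seed(seed)
  sc <- do.call(sim_scenario, c(list(hypothesis = hypothesis),
                                scenario_args))
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    panel <- simulate_panel(sc$n_hap, sc$n_variants, sc$ld_decay,
                            span = sc$cis_span)
    sim <- simulate_two_trait_gwas(panel, sc)
    cl <- coloc_abf(sim$exposure$records, sim$outcome$records,
                    priors = priors)
    rows[[i]] <- data.frame(pph0 = cl$pph0, pph1 = cl$pph1, pph2 = cl$pph2,
                            pph3 = cl$pph3, pph4 = cl$pph4,
                            n_snps = cl$n_snps)
  }
  do.call(rbind, rows)
}

#' Build a multi-protein synthetic study as a ready-to-run pipeline config
#'
#' Simulates `n_proteins` unlinked cis regions (one per chromosome) plus one
#' disease-susceptibility region with a direct case-control signal (so the
#' disease GWAS has genome-wide instruments of its own for bidirectional
#' MR). One protein (`causal_protein`) is forward-causal: its cis variant
#' drives its level, and the level drives disease risk, so its region also
#' colocalizes with the disease signal. The remaining proteins have cis
#' pQTLs but no disease effect. A replication exposure cohort is simulated
#' for every protein, and a benign annotation catalog plus a small Phe-MR
#' manifest are attached.
#'
#' Because the regions are unlinked, each region's marginal statistics are
#' computed on an independent cohort draw; effects from other regions are
#' absorbed into residual noise, which changes nothing at the per-variant
#' level.
#'
#' @param n_proteins number of proteins (default 5).
#' @param causal_protein index of the forward-causal protein (default 1).
#' @param seed integer seed.
#' @param n_replication replication exposure cohort size (default 35559).
#' @param scenario_args overrides for the causal protein's [sim_scenario]
#'   (defaults here: `h2_exposure = 0.1`, `mr_effect = 0.35` — a strong,
#'   clearly detectable target for integration runs).
#' @param thresholds threshold overrides for [pipeline_config].
#' @param outdir optional artifact directory.
#' @return A [pipeline_config] with a `truth` attribute naming the causal
#'   protein and its simulated effects.
#' @export
simulate_study <- function(n_proteins = 5, causal_protein = 1, seed = 1L,
                           n_replication = 35559,
                           scenario_args = list(), thresholds = list(),
                           outdir = NULL) {
  set.seed(seed)
  causal_defaults <- list(h2_exposure = 0.1, mr_effect = 0.35)
  causal_args <- utils::modifyList(causal_defaults, scenario_args)
  genes <- sprintf("PROT%d", seq_len(n_proteins))
  n_regions <- n_proteins + 1L          # last region: disease susceptibility

  panels <- vector("list", n_regions)
  scenarios <- vector("list", n_regions)
  for (q in seq_len(n_regions)) {
    hyp <- if (q == n_regions) "H2" else
      if (q == causal_protein) "forward_causal" else "null_mr"
    args <- if (q == causal_protein) causal_args else list()
    scenarios[[q]] <- do.call(sim_scenario,
                              c(list(hypothesis = hyp, n_variants = 60L),
                                args))
    panels[[q]] <- simulate_panel(scenarios[[q]]$n_hap, 60L,
                                  scenarios[[q]]$ld_decay,
                                  chrom = as.character(q),
                                  span = scenarios[[q]]$cis_span,
                                  id_start = (q - 1L) * 10000L + 1L)
  }

  sims <- lapply(seq_len(n_regions), function(q)
    simulate_two_trait_gwas(panels[[q]], scenarios[[q]]))

  # combined disease GWAS across all regions
  outcome_records <- do.call(rbind, lapply(sims, function(s)
    s$outcome$records))
  outcome <- summary_stats(outcome_records, trait_id = "disease",
                           trait_type = "case_control",
                           default_n_case = scenarios[[1]]$n_case,
                           default_n_control = scenarios[[1]]$n_control)

  # per-protein exposure (own region signal + null scans elsewhere) for the
  # discovery and replication cohorts
  null_scan <- function(panel, n) {
    G <- sample_genotypes(panel, n)
    scan <- linear_scan(G, stats::rnorm(n))
    scan_to_sumstats(panel, scan, eaf = colMeans(G) / 2, trait_id = "tmp",
                     trait_type = "quantitative", n = n)$records
  }
  build_exposure <- function(p, n, own_records) {
    other <- do.call(rbind, lapply(setdiff(seq_len(n_regions), p),
                                   function(q) null_scan(panels[[q]], n)))
    summary_stats(rbind(own_records, other), trait_id = genes[p],
                  trait_type = "quantitative", default_n = n)
  }
  exposure <- stats::setNames(lapply(seq_len(n_proteins), function(p)
    build_exposure(p, scenarios[[p]]$n_exposure,
                   sims[[p]]$exposure$records)), genes)
  replication <- stats::setNames(lapply(seq_len(n_proteins), function(p) {
    sc_rep <- scenarios[[p]]
    sc_rep$n_exposure <- n_replication
    rep_sim <- simulate_two_trait_gwas(panels[[p]], sc_rep,
                                       exposure_id = genes[p])
    build_exposure(p, n_replication, rep_sim$exposure$records)
  }), genes)

  # combined panel (independent blocks; one chromosome per region)
  panel <- ld_panel(
    haplotypes = do.call(cbind, lapply(panels, `[[`, "haplotypes")),
    sites = do.call(rbind, lapply(panels, function(pl) pl$sites)))

  proteins <- data.frame(
    gene = genes,
    chrom = as.character(seq_len(n_proteins)),
    anchor_pos = vapply(seq_len(n_proteins), function(p)
      panels[[p]]$sites$pos[scenarios[[p]]$causal_exposure], 0),
    stringsAsFactors = FALSE)

  # benign catalog: a few non-disqualifying published associations
  catalog <- annotation_catalog(data.frame(
    variant_id = panels[[1]]$sites$variant_id[1:2],
    trait_id = c("height", "some_protein"),
    pvalue = c(1e-10, 1e-9),
    trait_class = c("other", "protein"), stringsAsFactors = FALSE))

  # small Phe-MR manifest: the index disease plus a null disease re-drawn
  # over the same regions
  null_disease_records <- do.call(rbind, lapply(seq_len(n_regions),
    function(q) {
      sc0 <- scenarios[[q]]
      sc0$hypothesis <- "H0"
      sc0$mr_effect <- 0
      sim0 <- simulate_two_trait_gwas(panels[[q]], sc0,
                                      outcome_id = "null_disease")
      sim0$outcome$records
    }))
  phemr <- list(
    index_disease = outcome,
    null_disease = summary_stats(null_disease_records,
                                 trait_id = "null_disease",
                                 trait_type = "case_control",
                                 default_n_case = scenarios[[1]]$n_case,
                                 default_n_control =
                                   scenarios[[1]]$n_control))

  cfg <- pipeline_config(proteins = proteins, exposure = exposure,
                         outcome = outcome, panel = panel,
                         replication = replication, catalog = catalog,
                         phemr_outcomes = phemr, thresholds = thresholds,
                         seed = seed, outdir = outdir)
  attr(cfg, "truth") <- list(
    causal_protein = genes[causal_protein],
    causal_variant = sims[[causal_protein]]$truth$causal_exposure_id,
    mr_effect = scenarios[[causal_protein]]$mr_effect,
    h2_exposure = scenarios[[causal_protein]]$h2_exposure)
  cfg
}
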