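# Seeded generator of LD reference panels and paired exposure/outcome GWAS
# summary statistics with known ground truth.
#
# Haplotypes follow a first-order Markov copying process along the region:
# site j+1 copies site j's allele with probability ld_decay and otherwise
# draws a fresh allele at its own innovation frequency, so the correlation
# between adjacent sites is ~ld_decay (adjacent r^2 ~ ld_decay^2) and decays
# geometrically with distance. Cohort genotypes are drawn by pairing panel
# haplotypes; marginal summary statistics come from exact per-variant
# regressions on the simulated cohort (OLS for the quantitative exposure,
# maximum-likelihood logistic for the case-control outcome), so LD-induced
# shadow associations arise naturally.

# non-palindromic allele pairs cycled across sites
SIM_ALLELE_PAIRS <- matrix(c("A", "G", "C", "T", "G", "T", "A", "C"),
                           ncol = 2, byrow = TRUE)

#' Simulate an LD reference panel
#'
#' @param n_hap number of haplotypes (>= 100).
#' @param n_variants number of variant sites.
#' @param ld_decay adjacent-site copying probability in `[0, 1)`; adjacent
#'   r^2 is approximately `ld_decay^2`.
#' @param seed optional integer seed (fully reproducible panels).
#' @param chrom chromosome label.
#' @param start_pos base-pair position of the first site.
#' @param span base-pair extent of the region (sites are evenly spaced).
#' @param id_start first value of the rs-number sequence, letting multiple
#'   regions carry disjoint variant ids.
#' @return An [ld_panel] whose `sites` also carry `effect_allele` /
#'   `other_allele` columns (non-palindromic pairs).
#' @export
simulate_panel <- function(n_hap, n_variants, ld_decay, seed = NULL,
                           chrom = "1", start_pos = 1e6, span = 4e5,
                           id_start = 1L) {
  if (n_hap < 100) stopf("simulate_panel requires n_hap >= 100")
  if (n_variants < 1) stopf("simulate_panel requires n_variants >= 1")
  if (ld_decay < 0 || ld_decay >= 1) stopf("ld_decay must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  f_innov <- stats::runif(n_variants, 0.1, 0.9)
  H <- matrix(0L, n_hap, n_variants)
  H[, 1] <- stats::rbinom(n_hap, 1L, f_innov[1])
  if (n_variants > 1) {
    for (j in 2:n_variants) {
      copy <- stats::runif(n_hap) < ld_decay
      fresh <- stats::rbinom(n_hap, 1L, f_innov[j])
      H[, j] <- ifelse(copy, H[, j - 1], fresh)
    }
  }
  pos <- if (n_variants == 1) start_pos else
    round(seq(start_pos, start_pos + span, length.out = n_variants))
  pair <- SIM_ALLELE_PAIRS[(seq_len(n_variants) - 1) %%
                             nrow(SIM_ALLELE_PAIRS) + 1, , drop = FALSE]
  sites <- data.frame(
    variant_id = sprintf("rs%07d", id_start + seq_len(n_variants) - 1L),
    chrom = chrom, pos = pos,
    effect_allele = pair[, 1], other_allele = pair[, 2],
    stringsAsFactors = FALSE)
  colnames(H) <- sites$variant_id
  ld_panel(haplotypes = H, sites = sites)
}

#' Simulation scenario
#'
#' Bundles the generative conditions for one paired exposure/outcome
#' dataset. Hypotheses: `H0` (no causal variant for either trait), `H1`
#' (exposure only), `H2` (outcome only), `H3` (distinct causal variants),
#' `H4` (one shared causal variant with a direct effect on both traits),
#' `forward_causal` (a cis causal variant drives the exposure, and the
#' exposure drives the outcome with log-OR `mr_effect` per SD),
#' `reverse_causal` (disease liability drives the protein), `null_mr`
#' (exposure has its pQTL but no effect on the outcome).
#'
#' @param hypothesis one of the above.
#' @param n_variants sites in the region (defaults: 200 for the
#'   colocalization hypotheses, 60 otherwise).
#' @param ld_decay adjacent-site copying probability (default 0.9).
#' @param n_hap panel haplotypes (default 5000).
#' @param cis_span region extent in base pairs (default 4e5).
#' @param n_exposure exposure cohort size (default 7213).
#' @param n_case,n_control outcome cohort composition (defaults 20000 each;
#'   the cohort is simulated at ~50% prevalence so realized counts match in
#'   expectation).
#' @param h2_exposure variance in the exposure explained by its cis causal
#'   variant (default 0.05).
#' @param mr_effect true exposure -> outcome log-OR per SD (default 0.25
#'   under `forward_causal`, else 0).
#' @param beta_outcome direct per-allele log-OR of the outcome causal
#'   variant under H2/H3/H4 (default 0.15).
#' @param reverse_effect per-case shift of the protein (in SD) under
#'   `reverse_causal` (default 0.75).
#' @param causal_exposure,causal_outcome site indexes of the causal variants
#'   (defaults: 40% of the region; outcome at 75% under H3, shared
#'   otherwise).
#' @param seed optional integer seed.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(hypothesis = c("forward_causal", "null_mr",
                                        "reverse_causal", "H0", "H1", "H2",
                                        "H3", "H4"),
                         n_variants = NULL, ld_decay = 0.9, n_hap = 5000,
                         cis_span = 4e5, n_exposure = 7213,
                         n_case = 20000, n_control = 20000,
                         h2_exposure = 0.05, mr_effect = NULL,
                         beta_outcome = 0.15, reverse_effect = 0.75,
                         causal_exposure = NULL, causal_outcome = NULL,
                         seed = NULL) {
  hypothesis <- match.arg(hypothesis)
  coloc_like <- hypothesis %in% c("H0", "H1", "H2", "H3", "H4")
  n_variants <- n_variants %||% if (coloc_like) 200L else 60L
  mr_effect <- mr_effect %||%
    if (hypothesis == "forward_causal") 0.25 else 0
  stopifnot(n_variants >= 1, n_exposure > 0, n_case > 0, n_control > 0,
            h2_exposure > 0, h2_exposure < 1)
  causal_exposure <- causal_exposure %||% max(1L, round(0.4 * n_variants))
  causal_outcome <- causal_outcome %||%
    if (hypothesis == "H3") max(1L, round(0.75 * n_variants)) else
      causal_exposure
  structure(list(hypothesis = hypothesis, n_variants = n_variants,
                 ld_decay = ld_decay, n_hap = n_hap, cis_span = cis_span,
                 n_exposure = n_exposure, n_case = n_case,
                 n_control = n_control, h2_exposure = h2_exposure,
                 mr_effect = mr_effect, beta_outcome = beta_outcome,
                 reverse_effect = reverse_effect,
                 causal_exposure = causal_exposure,
                 causal_outcome = causal_outcome, seed = seed),
            class = "sim_scenario")
}

sample_genotypes <- function(panel, n) {
  H <- panel$haplotypes
  i1 <- sample.int(nrow(H), n, replace = TRUE)
  i2 <- sample.int(nrow(H), n, replace = TRUE)
  G <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
  storage.mode(G) <- "double"
  G
}

# exact per-variant simple linear regression (intercept + genotype),
# vectorized across variants
linear_scan <- function(G, y) {
  n <- length(y)
  gbar <- colMeans(G)
  yc <- y - mean(y)
  Sxx <- colSums(G^2) - n * gbar^2
  Sxy <- as.vector(crossprod(G, yc))
  Syy <- sum(yc^2)
  poly <- Sxx > 1e-10
  beta <- ifelse(poly, Sxy / Sxx, 0)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- ifelse(poly, sqrt(rss / (n - 2) / pmax(Sxx, 1e-300)), Inf)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[!poly] <- 1
  list(beta = beta, se = se, pvalue = pmin(pmax(p, 1e-300), 1))
}

# exact per-variant ML logistic regression (intercept + genotype).
# With genotype in {0,1,2} the likelihood depends only on the per-variant
# 3x2 genotype-by-status table, so the data are collapsed to those counts
# once and the Newton iterations run on them, vectorized across variants.
logistic_scan <- function(G, y, max_iter = 25, tol = 1e-9) {
  n <- length(y)
  m <- ncol(G)
  G2 <- G * G
  sg <- colSums(G)                       # n1 + 2 n2
  sg2 <- colSums(G2)                     # n1 + 4 n2
  cy <- as.vector(crossprod(G, y))       # c1 + 2 c2
  cy2 <- as.vector(crossprod(G2, y))     # c1 + 4 c2
  n2 <- (sg2 - sg) / 2
  n1 <- sg - 2 * n2
  n0 <- n - n1 - n2
  c2 <- (cy2 - cy) / 2
  c1 <- cy - 2 * c2
  c0 <- sum(y) - c1 - c2
  nk <- rbind(n0, n1, n2)
  ck <- rbind(c0, c1, c2)
  k <- c(0, 1, 2)

  poly <- (colMeans(G2) - colMeans(G)^2) > 1e-10
  a <- rep(stats::qlogis(mean(y)), m)
  b <- rep(0, m)
  se <- rep(Inf, m)
  det <- rep(0, m)
  S0 <- rep(0, m)
  ok <- poly
  for (it in seq_len(max_iter)) {
    eta <- outer(k, b) + rep(a, each = 3L)     # 3 x m
    mu <- 1 / (1 + exp(-eta))
    w <- nk * mu * (1 - mu)
    res <- ck - nk * mu
    S0 <- colSums(w)
    S1 <- colSums(k * w)
    S2 <- colSums(k * k * w)
    U0 <- colSums(res)
    U1 <- colSums(k * res)
    det <- S0 * S2 - S1^2
    ok <- poly & det > 1e-10
    da <- ifelse(ok, (S2 * U0 - S1 * U1) / det, 0)
    db <- ifelse(ok, (S0 * U1 - S1 * U0) / det, 0)
    a <- a + da
    b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  se[ok] <- sqrt(S0 / det)[ok]
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!ok] <- 1
  b[!ok] <- 0
  list(beta = b, se = se, pvalue = pmin(pmax(p, 1e-300), 1))
}

scan_to_sumstats <- function(panel, scan, eaf, trait_id, trait_type,
                             n, n_case = NA_real_, n_control = NA_real_) {
  s <- panel$sites
  finite <- is.finite(scan$se) & scan$se > 0
  rec <- data.frame(
    variant_id = s$variant_id, chrom = s$chrom, pos = s$pos,
    effect_allele = s$effect_allele, other_allele = s$other_allele,
    eaf = eaf, beta = scan$beta, se = ifelse(finite, scan$se, NA_real_),
    pvalue = scan$pvalue, n = n, n_case = n_case, n_control = n_control,
    stringsAsFactors = FALSE)
  summary_stats(rec[finite, , drop = FALSE], trait_id = trait_id,
                trait_type = trait_type, default_n = n,
                default_n_case = n_case, default_n_control = n_control)
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Generates individual-level data for two non-overlapping cohorts
#' (quantitative exposure; case-control outcome at ~50% prevalence), then
#' reduces each to per-variant marginal summary statistics by exact
#' regression (see the module header). The ground truth needed to score
#' every downstream decision is returned alongside.
#'
#' @param panel [ld_panel] from [simulate_panel] (alleles in its sites).
#' @param scenario [sim_scenario]; its `seed`, when set, makes the draw
#'   fully reproducible.
#' @param exposure_id,outcome_id trait labels.
#' @return list of class `sim_gwas`: `exposure` and `outcome`
#'   ([summary_stats]) and `truth` (list with the causal variant ids, true
#'   effects and the scenario).
#' @export
simulate_two_trait_gwas <- function(panel, scenario,
                                    exposure_id = "protein",
                                    outcome_id = "disease") {
  stopifnot(inherits(panel, "ld_panel"), inherits(scenario, "sim_scenario"),
            !is.null(panel$haplotypes))
  if (ncol(panel$haplotypes) != scenario$n_variants)
    stopf("panel has %d variants but scenario expects %d",
          ncol(panel$haplotypes), scenario$n_variants)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  hyp <- scenario$hypothesis
  ci <- scenario$causal_exposure
  co <- scenario$causal_outcome
  f_ci <- mean(panel$haplotypes[, ci])
  f_co <- mean(panel$haplotypes[, co])
  # per-allele effect giving variance h2 in a unit-variance exposure
  b_exp <- sqrt(scenario$h2_exposure / (2 * f_ci * (1 - f_ci)))

  exposure_has_qtl <- hyp %in% c("H1", "H3", "H4", "forward_causal",
                                 "null_mr")
  outcome_direct <- hyp %in% c("H2", "H3", "H4")

  gen_exposure <- function(G) {
    n <- nrow(G)
    if (hyp == "reverse_causal") {
      # protein responds to disease status; its pQTL is mediated
      eta <- scenario$beta_outcome * 2 * (G[, ci] - 2 * f_ci)
      d <- stats::rbinom(n, 1, stats::plogis(eta))
      return(scenario$reverse_effect * d +
               stats::rnorm(n, 0, sqrt(1 - scenario$h2_exposure)))
    }
    x <- stats::rnorm(n, 0, if (exposure_has_qtl)
      sqrt(1 - scenario$h2_exposure) else 1)
    if (exposure_has_qtl) x <- x + b_exp * (G[, ci] - 2 * f_ci)
    x
  }

  # exposure cohort
  Ge <- sample_genotypes(panel, scenario$n_exposure)
  xe <- gen_exposure(Ge)
  scan_e <- linear_scan(Ge, xe)
  exposure <- scan_to_sumstats(panel, scan_e, eaf = colMeans(Ge) / 2,
                               trait_id = exposure_id,
                               trait_type = "quantitative",
                               n = scenario$n_exposure)
  rm(Ge)

  # outcome cohort (non-overlapping)
  n_out <- scenario$n_case + scenario$n_control
  Go <- sample_genotypes(panel, n_out)
  eta <- rep(0, n_out)
  if (outcome_direct) eta <- eta + scenario$beta_outcome * (Go[, co] - 2 * f_co)
  if (hyp == "forward_causal" && scenario$mr_effect != 0)
    eta <- eta + scenario$mr_effect * gen_exposure(Go)
  if (hyp == "reverse_causal")
    eta <- eta + scenario$beta_outcome * 2 * (Go[, ci] - 2 * f_ci)
  yo <- stats::rbinom(n_out, 1, stats::plogis(eta))
  scan_o <- logistic_scan(Go, yo)
  outcome <- scan_to_sumstats(panel, scan_o, eaf = colMeans(Go) / 2,
                              trait_id = outcome_id,
                              trait_type = "case_control", n = n_out,
                              n_case = sum(yo), n_control = n_out - sum(yo))
  rm(Go)

  ids <- panel$sites$variant_id
  truth <- list(
    hypothesis = hyp,
    causal_exposure_id = if (exposure_has_qtl || hyp == "reverse_causal")
      ids[ci] else NA_character_,
    causal_outcome_id = if (outcome_direct || hyp == "reverse_causal")
      ids[co] else NA_character_,
    b_exposure_per_allele = if (exposure_has_qtl) b_exp else 0,
    mr_effect = scenario$mr_effect,
    beta_outcome = if (outcome_direct) scenario$beta_outcome else 0,
    expected_direction = if (hyp == "reverse_causal") "reverse" else
      "forward",
    scenario = scenario)
  structure(list(exposure = exposure, outcome = outcome, truth = truth),
            class = "sim_gwas")
}

#' @export
print.sim_gwas <- function(x, ...) {
  cat(sprintf("<sim_gwas> hypothesis %s: exposure %d variant(s), outcome %d\n",
              x$truth$hypothesis, nrow(x$exposure$records),
              nrow(x$outcome$records)))
  invisible(x)
}

#' Write a simulation truth sidecar as TSV
#' @param sim a [simulate_two_trait_gwas] result.
#' @param path output path.
#' @export
write_sim_truth <- function(sim, path) {
  t <- sim$truth
  df <- data.frame(
    hypothesis = t$hypothesis,
    causal_exposure_id = t$causal_exposure_id,
    causal_outcome_id = t$causal_outcome_id,
    b_exposure_per_allele = t$b_exposure_per_allele,
    mr_effect = t$mr_effect, beta_outcome = t$beta_outcome,
    expected_direction = t$expected_direction, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
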