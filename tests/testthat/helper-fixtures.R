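# Fixture builders shared across the suite. Everything is generated in code;
# sizes here are deliberately small (these are unit fixtures, not the
# calibration conditions).

# canonical variant record with overridable fields
make_records <- function(n = 3, ...) {
  out <- data.frame(
    variant_id = sprintf("rs%d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1000,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = rep(0.3, n),
    beta = seq(0.1, by = 0.05, length.out = n),
    se = rep(0.02, n),
    pvalue = rep(1e-10, n),
    n = rep(5000, n),
    n_case = NA_real_, n_control = NA_real_,
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  out
}

make_stats <- function(n = 3, trait_id = "trait",
                       trait_type = "quantitative", ...) {
  summary_stats(make_records(n, ...), trait_id = trait_id,
                trait_type = trait_type)
}

# small panel with prescribed pairwise r2 (block-free, via explicit matrix)
r2_panel <- function(r2, chrom = NULL, pos = NULL) {
  ids <- rownames(r2)
  sites <- data.frame(variant_id = ids,
                      chrom = chrom %||% rep("1", length(ids)),
                      pos = pos %||% seq_along(ids) * 1000,
                      stringsAsFactors = FALSE)
  ld_panel(r2 = r2, sites = sites)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent brute-force implementation of the greedy clumping rule:
# full r2 matrix up front, explicit set bookkeeping
clump_oracle <- function(candidates, panel, r2_max, window_kb) {
  cand <- candidates[candidates$variant_id %in% panel_variants(panel), ,
                     drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  r2 <- ld_r2(panel, cand$variant_id)
  remaining <- cand$variant_id
  kept <- character(0)
  ord <- cand$variant_id[order(cand$pvalue, cand$variant_id)]
  while (length(remaining) > 0) {
    index <- ord[ord %in% remaining][1]
    kept <- c(kept, index)
    remaining <- setdiff(remaining, index)
    i <- match(index, cand$variant_id)
    for (v in remaining) {
      j <- match(v, cand$variant_id)
      same_chr <- cand$chrom[i] == cand$chrom[j]
      close <- abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000
      if (same_chr && close && r2[i, j] > r2_max)
        remaining <- setdiff(remaining, v)
    }
  }
  kept
}

# exhaustive-configuration colocalization oracle: raw Bayes-factor products
# over every causal configuration (null, trait-1-only at i, trait-2-only at
# j, distinct pair (i, j), shared variant i)
coloc_oracle <- function(region1, region2, priors = coloc_priors(),
                         sd1 = 0.15, sd2 = 0.2) {
  shared <- intersect(region1$variant_id, region2$variant_id)
  r1 <- region1[match(shared, region1$variant_id), ]
  r2 <- region2[match(shared, region2$variant_id), ]
  abf <- function(beta, se, sd0) {
    V <- se^2; W <- sd0^2
    sqrt(V / (V + W)) * exp((beta / se)^2 * (W / (V + W)) / 2)
  }
  bf1 <- abf(r1$beta, r1$se, sd1)
  bf2 <- abf(r2$beta, r2$se, sd2)
  m <- length(shared)
  s0 <- 1
  s1 <- sum(priors$p1 * bf1)
  s2 <- sum(priors$p2 * bf2)
  s3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) s3 <- s3 + priors$p1 * priors$p2 * bf1[i] * bf2[j]
  s4 <- sum(priors$p12 * bf1 * bf2)
  tot <- s0 + s1 + s2 + s3 + s4
  c(pph0 = s0, pph1 = s1, pph2 = s2, pph3 = s3, pph4 = s4) / tot
}

# tiny simulated dataset for module-level checks (fast, not study scale)
small_sim <- function(hypothesis = "forward_causal", seed = 1, ...) {
  args <- utils::modifyList(
    list(hypothesis = hypothesis, n_variants = 30, n_hap = 400,
         n_exposure = 1500, n_case = 2500, n_control = 2500, seed = seed),
    list(...))
  sc <- do.call(sim_scenario, args)
  panel <- simulate_panel(sc$n_hap, sc$n_variants, sc$ld_decay, seed = seed,
                          span = sc$cis_span)
  list(panel = panel, scenario = sc,
       sim = simulate_two_trait_gwas(panel, sc))
}
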