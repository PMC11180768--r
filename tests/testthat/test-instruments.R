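test_that("instrument F-statistic is the squared z-score", {
  expect_equal(f_statistic(0.5, 0.05), 100)
  expect_equal(f_statistic(0.1, 0.1), 1)
  expect_equal(f_statistic(0.0316228, 0.01), 10, tolerance = 1e-5)
  expect_error(f_statistic(0.1, 0), "se > 0")
})

test_that("the weak-instrument boundary keeps F exactly 10", {
  # one cis variant with beta/se chosen so F = 10 exactly
  ss <- make_stats(1, beta = 0.1 * sqrt(10), se = 0.1, pvalue = 1e-12)
  panel <- r2_panel(matrix(1, 1, 1, dimnames = list("rs1", "rs1")))
  reg <- cis_region("G1", "1", 1000, cis_radius = 1e5)
  inst <- select_instruments(ss, reg, panel)
  expect_equal(nrow(inst), 1)          # F < 10 excluded, F = 10 retained
  inst2 <- select_instruments(ss, reg, panel,
                              params = instrument_params(f_min = 10.1))
  expect_equal(nrow(inst2), 0)
})

test_that("clumping keeps the smallest-p index and drops its LD neighbours", {
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
               dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  panel <- r2_panel(r2, pos = c(1000, 2000))
  cand <- data.frame(variant_id = c("rs1", "rs2"), chrom = "1",
                     pos = c(1000, 2000), pvalue = c(1e-10, 1e-8),
                     stringsAsFactors = FALSE)
  kept <- greedy_clump(cand, panel, r2_max = 0.001, window_kb = 10000)
  expect_equal(kept$variant_id, "rs1")

  # different chromosomes: the window never spans chromosomes
  panel2 <- r2_panel(r2, chrom = c("1", "2"), pos = c(1000, 2000))
  cand2 <- cand
  cand2$chrom <- c("1", "2")
  kept2 <- greedy_clump(cand2, panel2, r2_max = 0.001, window_kb = 10000)
  expect_setequal(kept2$variant_id, c("rs1", "rs2"))
})

test_that("clumping agrees with a brute-force oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- 50
    panel <- simulate_panel(200, m, ld_decay = 0.8, span = 2e5)
    cand <- data.frame(variant_id = panel$sites$variant_id,
                       chrom = panel$sites$chrom, pos = panel$sites$pos,
                       pvalue = runif(m, 1e-12, 1e-4),
                       stringsAsFactors = FALSE)
    kept <- greedy_clump(cand, panel, r2_max = 0.1, window_kb = 50)
    oracle <- clump_oracle(cand, panel, r2_max = 0.1, window_kb = 50)
    expect_setequal(kept$variant_id, oracle)
  }
})

test_that("no two retained instruments violate the clumping constraint", {
  set.seed(99)
  panel <- simulate_panel(300, 40, ld_decay = 0.9, span = 1e5)
  cand <- data.frame(variant_id = panel$sites$variant_id,
                     chrom = panel$sites$chrom, pos = panel$sites$pos,
                     pvalue = runif(40, 1e-12, 1e-4),
                     stringsAsFactors = FALSE)
  kept <- greedy_clump(cand, panel, r2_max = 0.05, window_kb = 10000)
  if (nrow(kept) > 1) {
    r2 <- ld_r2(panel, kept$variant_id)
    diag(r2) <- 0
    expect_true(all(r2 <= 0.05))
  }
})

test_that("selection pipeline applies cis, significance, clump and F filters in order", {
  ss <- make_stats(1, beta = 0.5, se = 0.04, pvalue = 1e-12)
  panel <- r2_panel(matrix(1, 1, 1, dimnames = list("rs1", "rs1")))
  reg <- cis_region("G1", "1", 1000, cis_radius = 1e5)
  inst <- select_instruments(ss, reg, panel)
  expect_equal(nrow(inst), 1)
  expect_true(inst$is_cis && inst$clump_index)
  expect_gt(inst$f_stat, 100)

  # sub-genome-wide significance: empty result
  ss2 <- make_stats(1, pvalue = 1e-6)
  expect_equal(nrow(select_instruments(ss2, reg, panel)), 0)
  # p exactly at the threshold is excluded (strict <)
  ss3 <- make_stats(1, pvalue = 5e-8)
  expect_equal(nrow(select_instruments(ss3, reg, panel)), 0)
  # chromosome absent from the stats: empty with a warning
  reg2 <- cis_region("G2", "17", 1000, cis_radius = 1e5)
  expect_warning(out <- select_instruments(ss, reg2, panel), "absent")
  expect_equal(nrow(out), 0)
})

test_that("selection recovers the causal variant (or a high-LD proxy) in simulation", {
  s <- small_sim("forward_causal", seed = 5)
  reg <- cis_region("G1", "1",
                    s$panel$sites$pos[s$scenario$causal_exposure],
                    cis_radius = 1e6)
  inst <- select_instruments(s$sim$exposure, reg, s$panel)
  expect_equal(nrow(inst), 1)          # r2_max 0.001 leaves one index SNP
  r2_with_causal <- ld_r2(s$panel, inst$variant_id,
                          s$sim$truth$causal_exposure_id)[1, 1]
  expect_gt(r2_with_causal, 0.8)
})

test_that("tightening any threshold never increases the instrument count", {
  s <- small_sim("forward_causal", seed = 8)
  reg <- cis_region("G1", "1",
                    s$panel$sites$pos[s$scenario$causal_exposure],
                    cis_radius = 1e6)
  base <- instrument_params(p_threshold = 1e-4, r2_max = 0.5,
                            window_kb = 100, f_min = 0)
  n_base <- nrow(select_instruments(s$sim$exposure, reg, s$panel, base))
  for (tight in list(instrument_params(p_threshold = 5e-8, r2_max = 0.5,
                                       window_kb = 100, f_min = 0),
                     instrument_params(p_threshold = 1e-4, r2_max = 0.01,
                                       window_kb = 100, f_min = 0),
                     instrument_params(p_threshold = 1e-4, r2_max = 0.5,
                                       window_kb = 100, f_min = 30))) {
    expect_lte(nrow(select_instruments(s$sim$exposure, reg, s$panel,
                                       tight)), n_base)
  }
})

test_that("input row order never changes the selection", {
  s <- small_sim("forward_causal", seed = 13)
  reg <- cis_region("G1", "1",
                    s$panel$sites$pos[s$scenario$causal_exposure],
                    cis_radius = 1e6)
  params <- instrument_params(p_threshold = 1e-4, r2_max = 0.3,
                              window_kb = 100, f_min = 0)
  a <- select_instruments(s$sim$exposure, reg, s$panel, params)
  shuffled <- s$sim$exposure
  set.seed(2)
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  b <- select_instruments(shuffled, reg, s$panel, params)
  expect_equal(a$variant_id, b$variant_id)
})
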