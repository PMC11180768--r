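mk_catalog <- function(...) {
  annotation_catalog(data.frame(..., stringsAsFactors = FALSE))
}

mk_instruments <- function(ids) {
  cbind(make_records(length(ids), variant_id = ids),
        f_stat = 100, is_cis = TRUE, clump_index = TRUE)
}

test_that("the pleiotropy scan drops disease/risk-factor-associated instruments", {
  inst <- mk_instruments(c("rs1", "rs2"))
  cat1 <- mk_catalog(variant_id = "rs1", trait_id = "bmi",
                     pvalue = 1e-9, trait_class = "risk_factor")
  res <- phenoscan_filter(inst, cat1)
  expect_equal(res$instruments$variant_id, "rs2")
  expect_equal(res$n_dropped, 1)
  expect_true(res$phenoscan_pass)

  # association above the threshold is not disqualifying
  cat2 <- mk_catalog(variant_id = "rs1", trait_id = "bmi",
                     pvalue = 1e-5, trait_class = "risk_factor")
  res2 <- phenoscan_filter(inst, cat2)
  expect_equal(nrow(res2$instruments), 2)

  # 'other'-class associations never drop instruments
  cat3 <- mk_catalog(variant_id = "rs1", trait_id = "height",
                     pvalue = 1e-20, trait_class = "other")
  expect_equal(nrow(phenoscan_filter(inst, cat3)$instruments), 2)
})

test_that("hub proteins are flagged but their instruments retained", {
  inst <- mk_instruments("rs1")
  hub_cat <- mk_catalog(
    variant_id = rep("rs1", 3),
    trait_id = c("protA", "protB", "protC"),
    pvalue = rep(1e-10, 3), trait_class = rep("protein", 3))
  res <- phenoscan_filter(inst, hub_cat)
  expect_true(res$hub_flag)
  expect_false(res$phenoscan_pass)
  expect_equal(nrow(res$instruments), 1)   # retained for estimation
  expect_setequal(res$hub_proteins, c("protA", "protB", "protC"))

  # a single protein association is not a hub
  one_cat <- mk_catalog(variant_id = "rs1", trait_id = "protA",
                        pvalue = 1e-10, trait_class = "protein")
  expect_true(phenoscan_filter(inst, one_cat)$phenoscan_pass)
})

test_that("the phenome-wide screen classifies by direction consistency", {
  exp <- make_stats(1, beta = 0.5, se = 0.02, pvalue = 1e-12)
  inst <- mk_instruments("rs1")
  mk_out <- function(beta, id) make_stats(1, beta = beta, se = 0.02,
                                          trait_id = id)
  outs <- list(
    same_dir = mk_out(0.2, "same_dir"),       # strong, same direction
    opp_dir = mk_out(-0.2, "opp_dir"),        # strong, opposite
    weak = mk_out(0.001, "weak"))             # not significant
  # index effect is risk-increasing
  ph <- phemr_screen(inst, exp, outs, index_beta = 0.4)
  expect_equal(ph$classification[ph$outcome == "same_dir"], "benefit")
  expect_equal(ph$classification[ph$outcome == "opp_dir"], "adverse")
  expect_equal(ph$classification[ph$outcome == "weak"], "none")
  expect_false(ph$significant[ph$outcome == "weak"])
  expect_equal(attr(ph, "threshold"), 0.05 / 3)

  # outcome ordering cannot change the classification counts
  ph_rev <- phemr_screen(inst, exp, rev(outs), index_beta = 0.4)
  expect_equal(sort(table(ph$classification)),
               sort(table(ph_rev$classification)))
})

test_that("screened outcomes without usable instruments get status records", {
  exp <- make_stats(1, beta = 0.5, se = 0.02, pvalue = 1e-12)
  inst <- mk_instruments("rs1")
  empty_out <- make_stats(1, variant_id = "rs999", trait_id = "nodata")
  ph <- phemr_screen(inst, exp, list(nodata = empty_out), index_beta = 0.4)
  expect_equal(ph$status, "lack_of_data")
  expect_equal(ph$classification, "none")
})

test_that("same-variant replication on the discovery cohort reproduces discovery", {
  s <- small_sim("forward_causal", seed = 17)
  reg <- cis_region("G1", "1",
                    s$panel$sites$pos[s$scenario$causal_exposure],
                    cis_radius = 1e6)
  inst <- select_instruments(s$sim$exposure, reg, s$panel)
  pairs <- harmonize(s$sim$exposure, s$sim$outcome, inst$variant_id)
  disc <- mr_estimate_pairs(pairs)
  rr <- replicate_estimate(inst, disc$beta,
                           replication_stats = s$sim$exposure,
                           outcome = s$sim$outcome,
                           strategy = "same_variant", threshold = 0.05)
  expect_equal(rr$estimate$beta, disc$beta)
  expect_equal(rr$estimate$pvalue, disc$pvalue)
})

test_that("replication statuses cover missing data, incompatible alleles, and failure", {
  inst <- mk_instruments("rs1")
  outcome <- make_stats(1, beta = 0.1, se = 0.02, trait_id = "out")

  # replication exposure lacks the discovery variant
  rep_missing <- make_stats(1, variant_id = "rs42")
  rr1 <- replicate_estimate(inst, 0.3, rep_missing, outcome,
                            strategy = "same_variant", threshold = 0.0045)
  expect_equal(rr1$status, "lack_of_data")

  # alleles incompatible between replication exposure and outcome
  rep_bad <- make_stats(1, effect_allele = "C", other_allele = "T")
  rr2 <- replicate_estimate(inst, 0.3, rep_bad, outcome,
                            strategy = "same_variant", threshold = 0.0045)
  expect_equal(rr2$status, "incompatible_alleles")

  # strong replication in the discovery direction passes
  rep_ok <- make_stats(1, beta = 0.5, se = 0.02)
  rr3 <- replicate_estimate(inst, 0.3, rep_ok, outcome,
                            strategy = "same_variant", threshold = 0.0045)
  expect_equal(rr3$status, "passed")
  expect_lt(rr3$estimate$pvalue, 0.0045)

  # p-value above the per-outcome threshold fails (0.0168 vs 0.0045 case)
  rep_weak <- make_stats(1, beta = 0.5, se = 0.02)
  out_weak <- make_stats(1, beta = 0.024, se = 0.01, trait_id = "out")
  rr4 <- replicate_estimate(inst, 0.3, rep_weak, out_weak,
                            strategy = "same_variant", threshold = 0.0045)
  expect_equal(rr4$status, "failed")
  expect_gt(rr4$estimate$pvalue, 0.0045)

  # direction reversal fails even when nominally significant
  rr5 <- replicate_estimate(inst, -0.3, rep_ok, outcome,
                            strategy = "same_variant", threshold = 0.0045)
  expect_equal(rr5$status, "failed")
})

test_that("significant-variant replication re-selects instruments from the replication cohort", {
  s <- small_sim("forward_causal", seed = 23)
  reg <- cis_region("G1", "1",
                    s$panel$sites$pos[s$scenario$causal_exposure],
                    cis_radius = 1e6)
  inst <- select_instruments(s$sim$exposure, reg, s$panel)
  # an independent replication draw of the same scenario
  sc_rep <- s$scenario
  sc_rep$seed <- 24
  rep_sim <- simulate_two_trait_gwas(s$panel, sc_rep)
  rr <- replicate_estimate(inst, 0.25, rep_sim$exposure, s$sim$outcome,
                           strategy = "significant_variant",
                           threshold = 0.05, region = reg,
                           panel = s$panel)
  expect_true(rr$status %in% c("passed", "failed"))
  expect_false(is.null(rr$estimate))
})

test_that("the evidence verdict is the conjunction of all filters", {
  base <- data.frame(
    protein = c("A", "B", "C"), outcome = "BC",
    discovery_significant = TRUE, steiger_pass = TRUE,
    bidirectional_pass = TRUE, phenoscan_pass = TRUE,
    coloc_pass = c(TRUE, FALSE, TRUE),
    replication_significant_pass = TRUE,
    replication_same_pass = c(TRUE, TRUE, NA),
    stringsAsFactors = FALSE)
  ev <- evidence_summary(base)
  expect_equal(ev$verdict, c("YES", "NO", "NO"))  # NA (lack of data) vetoes
})

test_that("the published-results digest replays to its printed counts", {
  digest <- read_evidence_digest(
    system.file("extdata", "published_targets_digest.tsv", package = "pqtlmr"))
  expect_equal(nrow(digest), 16)
  ev <- evidence_replay(digest, m_discovery = 2004)
  # 11 overall-disease rows clear the proteome-wide Bonferroni threshold
  expect_equal(sum(ev$discovery_significant[digest$outcome ==
                                              "BC_overall"]), 11)
  # 7 of 16 printed posteriors clear PPH4 > 0.7
  expect_equal(sum(ev$coloc_pass_pph4, na.rm = TRUE), 7)
  # the conjunction of printed flags leaves exactly 5 evidence-complete rows
  expect_equal(sum(ev$verdict == "YES"), 5)
  expect_setequal(ev$protein[ev$verdict == "YES"],
                  c("TLR1", "A4GALT", "SNUPN", "CTSF"))
  # the replayed verdicts match the printed verdict column row by row
  expect_equal(ev$verdict, digest$verdict_printed)
})
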