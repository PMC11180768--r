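test_that("canonical files parse identically through a dialect mapping", {
  ss <- make_stats(3)
  canon <- tempfile(fileext = ".tsv")
  write_sumstats(ss, canon)
  back <- read_sumstats(canon, trait_id = "trait")
  expect_equal(back$records, ss$records)

  # same content under foreign headers plus a dialect map
  foreign <- ss$records[c("variant_id", "chrom", "pos", "effect_allele",
                          "other_allele", "eaf", "beta", "se", "pvalue",
                          "n")]
  names(foreign) <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "b", "SE",
                      "P", "N")
  fpath <- tempfile(fileext = ".tsv")
  write.table(foreign, fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mapped <- read_sumstats(
    fpath, trait_id = "trait",
    dialect = c(variant_id = "SNP", chrom = "CHR", pos = "BP",
                effect_allele = "A1", other_allele = "A2", eaf = "FRQ",
                beta = "b", se = "SE", pvalue = "P", n = "N"))
  expect_equal(mapped$records[1:10], ss$records[1:10])
})

test_that("invariant-violating rows are rejected with a count, not dropped silently", {
  rec <- make_records(4)
  rec$se[2] <- 0                       # violates se > 0
  rec$other_allele[3] <- "G"           # same as effect allele
  ss <- summary_stats(rec, trait_id = "x")
  expect_equal(nrow(ss$records), 2)
  expect_equal(attr(ss, "n_rejected"), 2)

  # all-invalid file errors out rather than returning an empty object
  rec_bad <- make_records(2, se = c(0, -1))
  path <- tempfile(fileext = ".tsv")
  write.table(rec_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "zero valid")
})

test_that("missing mandatory columns raise a configuration error naming them", {
  rec <- make_records(2)
  rec$se <- NULL
  path <- tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "se")
})

test_that("indels and multi-allelic codes are rejected at parse time", {
  rec <- make_records(3)
  rec$effect_allele[1] <- "AT"
  rec$other_allele[2] <- "-"
  ss <- summary_stats(rec)
  expect_equal(ss$records$variant_id, "rs3")
  expect_equal(attr(ss, "n_rejected"), 2)
})

test_that("harmonization aligns same, swapped and incompatible codings", {
  exp <- make_stats(3, effect_allele = c("A", "A", "A"),
                    other_allele = c("G", "G", "G"),
                    beta = c(0.2, 0.2, 0.2), eaf = c(0.3, 0.3, 0.3))
  out_rec <- make_records(3, effect_allele = c("A", "G", "C"),
                          other_allele = c("G", "A", "T"),
                          beta = c(0.1, 0.1, 0.1), eaf = c(0.3, 0.3, 0.3))
  out <- summary_stats(out_rec, trait_id = "out")
  h <- harmonize(exp, out)
  expect_equal(h$status, c("ok", "ok", "dropped_incompatible"))
  expect_equal(h$flipped, c(FALSE, TRUE, FALSE))
  expect_equal(h$beta_out[1], 0.1)
  expect_equal(h$beta_out[2], -0.1)    # sign flip
  expect_equal(h$eaf_out[2], 0.7)      # frequency complement
  expect_true(is.na(h$beta_out[3]))    # dropped pairs carry no estimates
})

test_that("palindromic variants obey the frequency-ambiguity rule", {
  pal_exp <- function(eaf) make_stats(1, effect_allele = "A",
                                      other_allele = "T", eaf = eaf)
  pal_out <- function(eaf) make_stats(1, effect_allele = "A",
                                      other_allele = "T", eaf = eaf,
                                      trait_id = "out")
  # eaf = 0.5 sits inside the ambiguity band: always dropped
  h <- harmonize(pal_exp(0.5), pal_out(0.2))
  expect_equal(h$status, "dropped_palindromic")
  # both frequencies clear of the band and on the same side: kept
  h2 <- harmonize(pal_exp(0.2), pal_out(0.25))
  expect_equal(h2$status, "ok")
  # opposite sides of 0.5: strand flip suspected, dropped
  h3 <- harmonize(pal_exp(0.2), pal_out(0.8))
  expect_equal(h3$status, "dropped_palindromic")
  # missing outcome frequency: dropped
  h4 <- harmonize(pal_exp(0.2), pal_out(NA_real_))
  expect_equal(h4$status, "dropped_palindromic")
  # boundary: exactly at the band edge is not "farther than" the limit
  h5 <- harmonize(pal_exp(0.42), pal_out(0.2),
                  palindromic_eaf_limit = 0.42)
  expect_equal(h5$status, "dropped_palindromic")
})

test_that("ids absent from the outcome get a distinct missing status", {
  exp <- make_stats(3)
  out <- make_stats(2, trait_id = "out")
  h <- harmonize(exp, out)
  expect_equal(h$status[3], "missing_outcome")
  expect_error(harmonize(exp, out, variant_ids = "rs99"),
               "absent from exposure")
})

test_that("harmonization is idempotent", {
  exp <- make_stats(4, effect_allele = c("A", "C", "G", "T"),
                    other_allele = c("G", "T", "A", "C"))
  out_rec <- make_records(4, effect_allele = c("G", "C", "G", "C"),
                          other_allele = c("A", "T", "A", "T"),
                          beta = c(0.1, -0.2, 0.3, 0.05),
                          eaf = c(0.2, 0.4, 0.6, 0.8))
  out <- summary_stats(out_rec, trait_id = "out")
  h1 <- harmonize(exp, out)
  ok1 <- h1[h1$status == "ok", ]
  # rebuild an outcome file from the harmonized records and harmonize again
  out2 <- summary_stats(data.frame(
    variant_id = ok1$variant_id, chrom = ok1$chrom, pos = ok1$pos,
    effect_allele = ok1$effect_allele, other_allele = ok1$other_allele,
    eaf = ok1$eaf_out, beta = ok1$beta_out, se = ok1$se_out,
    pvalue = ok1$pvalue_out, n = ok1$n_out,
    stringsAsFactors = FALSE), trait_id = "out2")
  h2 <- harmonize(exp, out2, variant_ids = ok1$variant_id)
  expect_equal(h2$beta_out, ok1$beta_out)
  expect_equal(h2$eaf_out, ok1$eaf_out)
  expect_false(any(h2$flipped))
})

test_that("flipping the outcome file's allele coding leaves MR estimates identical", {
  set.seed(31)
  exp <- make_stats(5, beta = rnorm(5, 0.3, 0.05), se = rep(0.02, 5))
  out_rec <- make_records(5, beta = rnorm(5, 0.05, 0.02),
                          se = rep(0.015, 5), eaf = runif(5, 0.1, 0.45))
  out <- summary_stats(out_rec, trait_id = "out")
  flipped_rec <- out_rec
  flipped_rec$effect_allele <- out_rec$other_allele
  flipped_rec$other_allele <- out_rec$effect_allele
  flipped_rec$beta <- -out_rec$beta
  flipped_rec$eaf <- 1 - out_rec$eaf
  out_flipped <- summary_stats(flipped_rec, trait_id = "out")

  est1 <- mr_estimate_pairs(harmonize(exp, out))
  est2 <- mr_estimate_pairs(harmonize(exp, out_flipped))
  expect_equal(est1$beta, est2$beta)
  expect_equal(est1$se, est2$se)
  expect_equal(est1$pvalue, est2$pvalue)
})
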