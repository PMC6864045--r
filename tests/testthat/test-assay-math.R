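test_that("ddPCR frequency implements the Poisson two-copy formula", {
  expect_equal(ddpcrTranslocationFrequency(10000, 0, 5000), 0)
  ## worked example: lambda_fam = 1.0005e-3, lambda_hex = 0.69315
  f <- ddpcrTranslocationFrequency(10000, 10, 5000)
  expect_equal(f, 100 * 2 * (-log(1 - 0.001)) / (-log(0.5)))
  expect_equal(round(f, 4), 0.2887)
  ## error states
  expect_error(ddpcrTranslocationFrequency(1000, 5, 0), "no reference")
  expect_error(ddpcrTranslocationFrequency(1000, 1000, 500), "saturated")
  expect_error(ddpcrTranslocationFrequency(1000, 5, 1000), "saturated")
  expect_error(ddpcrTranslocationFrequency(0, 0, 0), "positive")
  ## selectable fractional-abundance variant
  fa <- ddpcrTranslocationFrequency(10000, 10, 5000,
                                    variant = "fractional_abundance")
  lam_f <- -log(1 - 0.001); lam_h <- -log(0.5)
  expect_equal(fa, 100 * 2 * lam_f / (lam_f + lam_h))
})

test_that("ddPCR frequency is monotone and linear in the rare-event limit", {
  n <- 20000
  f1 <- ddpcrTranslocationFrequency(n, 10, 8000)
  f2 <- ddpcrTranslocationFrequency(n, 20, 8000)
  expect_gt(f2, f1)
  expect_lt(ddpcrTranslocationFrequency(n, 10, 9000), f1)
  ## doubling k_fam approximately doubles the frequency
  expect_equal(f2 / f1, 2, tolerance = 1e-3)
  ## first-order agreement with the linearization 2*(k/n)/lambda_hex
  lam_h <- -log(1 - 8000 / n)
  expect_equal(f1, 100 * 2 * (10 / n) / lam_h, tolerance = 1e-3)
})

test_that("PD-1 normalization matches the control-ratio formulas exactly", {
  ## r = 1 is the identity
  id <- normalizePd1(37.2, 60.1, 1)
  expect_equal(id$f_pos, 37.2)
  expect_equal(id$f_neg, 60.1)
  ## worked example
  ex <- normalizePd1(40, 60, 0.8)
  expect_equal(ex$f_pos, 48)
  expect_equal(ex$f_neg, 52)
  ## conservation holds exactly for randomized valid inputs
  set.seed(42)
  for (i in 1:200) {
    fp <- runif(1, 0, 80); fn <- runif(1, 0, 100 - fp)
    r <- runif(1, 0.1, 3)
    res <- suppressWarnings(normalizePd1(fp, fn, r))
    expect_equal(res$f_pos + res$f_neg, fp + fn, tolerance = 1e-12)
  }
  ## out-of-range results warn, clamping only on request
  expect_warning(oor <- normalizePd1(80, 10, 3), "outside")
  expect_lt(oor$f_pos, 0)    # r > 1 shifts mass out of the positive gate
  expect_warning(cl <- normalizePd1(80, 10, 3, clamp = TRUE), "clamped")
  expect_equal(cl$f_pos, 0)
  expect_equal(cl$f_neg, 100)
  expect_error(normalizePd1(70, 40, 1), "exceeds 100")
  expect_error(normalizePd1(10, 20, 0), "positive")
})

test_that("RNA off-target ranking scores percent-maximal expression", {
  rec <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
    reads_cd4 = c(100, 90, 80, 70, 60, 50, 200, 10),
    reads_cd8 = c(100, 90, 80, 70, 60, 50, 200, 0),
    previously_edited = c(rep(TRUE, 6L), FALSE, TRUE))
  top <- rankRnaOtCandidates(rec, topN = 5)
  ## the maximal product (g7) defines the denominator even when filtered out
  expect_equal(max(rankRnaOtCandidates(rec, topN = 8)$score),
               (100 * 100) / (200 * 200))
  ## sort oracle: five largest-product previously edited genes
  expect_equal(top$gene, c("g1", "g2", "g3", "g4", "g5"))
  expect_true(all(diff(top$score) <= 0))
  ## zero reads in either compartment scores 0
  expect_equal(rankRnaOtCandidates(rec, topN = 8)$score[
    rankRnaOtCandidates(rec, topN = 8)$gene == "g8"], 0)
  ## self-normalization: unique max scores exactly 1
  rec2 <- rec[rec$gene != "g7", ]
  expect_equal(max(rankRnaOtCandidates(rec2, topN = 3)$score), 1)
  ## deterministic ties by gene id
  tie <- data.frame(gene = c("b", "a"), reads_cd4 = c(10, 10),
                    reads_cd8 = c(10, 10), previously_edited = TRUE)
  expect_equal(rankRnaOtCandidates(tie, topN = 2)$gene, c("a", "b"))
  expect_error(rankRnaOtCandidates(
    data.frame(gene = "g", reads_cd4 = 0, reads_cd8 = 0,
               previously_edited = TRUE)), "zero")
})

test_that("ddPCR tables gain a computed frequency column", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay\tn\tk_fam\tk_hex",
               "TRAC_B2M\t10000\t10\t5000",
               "B2M_PDCD1\t10000\t0\t5000"), tsv)
  d <- readDdpcrTable(tsv)
  expect_equal(round(d$frequency_pct, 4), c(0.2887, 0))
})
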