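test_that("the generator is closed under its own truth table", {
  ## every planted feature is recovered, and nothing else
  r <- makeSyntheticLocus(seed = 91, nExons = 3, plantDonorGuides = 1L,
                          plantAcceptorGuides = 2L,
                          plantPmstopCodons = c("CAA", "TGG"))
  expect_equal(length(r$guides), nrow(r$plant))
  expect_setequal(paste(r$truth_guides$class, r$truth_guides$target),
                  paste(r$plant$class, r$plant$target))
  expect_true(all(r$truth_guides$critical_pos != ""))

  ## zero planted PAMs -> no designable guides at all
  r0 <- makeSyntheticLocus(seed = 92, plantDonorGuides = integer())
  expect_length(findSpliceGuides(r0$tm, r0$genome), 0L)
  expect_length(findPmstopGuides(r0$tm, r0$genome), 0L)
})

test_that("identical seeds give byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a <- makeSyntheticLocus(seed = 93, plantDonorGuides = 1L,
                          plantPmstopCodons = "CAA", dir = d1, prefix = "x")
  b <- makeSyntheticLocus(seed = 93, plantDonorGuides = 1L,
                          plantPmstopCodons = "CAA", dir = d2, prefix = "x")
  for (f in names(a$files)) {
    expect_identical(readBin(a$files[[f]], "raw", 1e6),
                     readBin(b$files[[f]], "raw", 1e6), label = f)
  }
  ## and a different seed gives a different locus
  c_ <- makeSyntheticLocus(seed = 94, plantDonorGuides = 1L,
                           plantPmstopCodons = "CAA")
  expect_false(identical(as.character(a$genome[[1L]]),
                         as.character(c_$genome[[1L]])))
})

test_that("simulated knockout calls honor rates and seed", {
  m1 <- simulateKoCalls(c(a = 1, b = 1, c = 1), 50, seed = 1)
  expect_true(all(m1))
  expect_equal(dim(m1), c(50L, 3L))
  m0 <- simulateKoCalls(c(a = 0), 50, seed = 1)
  expect_false(any(m0))
  expect_identical(simulateKoCalls(c(a = .3, b = .7), 1000, seed = 9),
                   simulateKoCalls(c(a = .3, b = .7), 1000, seed = 9))
  expect_false(identical(simulateKoCalls(c(a = .5), 1000, seed = 1),
                         simulateKoCalls(c(a = .5), 1000, seed = 2)))
  ## rates recovered within binomial error (3 sigma)
  m <- simulateKoCalls(c(a = .9, b = .5), 20000, seed = 5)
  expect_lt(abs(mean(m[, "a"]) - 0.9), 3 * sqrt(.9 * .1 / 20000))
  expect_lt(abs(mean(m[, "b"]) - 0.5), 3 * sqrt(.25 / 20000))
  expect_error(simulateKoCalls(c(a = 1.2), 10, 1), "\\[0, 1\\]")
})

test_that("simulated ddPCR counts follow the generative model", {
  z <- simulateDdpcr(0, 20000, 0.7, seed = 3)
  expect_equal(z$k_fam, 0L)
  expect_identical(simulateDdpcr(1, 20000, 0.7, seed = 4),
                   simulateDdpcr(1, 20000, 0.7, seed = 4))
  ## occupancy near the expected Poisson fraction
  s <- simulateDdpcr(2, 20000, 0.7, seed = 5)
  expect_lt(abs(s$k_hex / s$n - (1 - exp(-0.7))), 0.02)
  ## estimator variability shrinks with droplet count
  est <- function(n, seeds) vapply(seeds, function(sd) {
    x <- simulateDdpcr(2, n, 0.7, seed = sd)
    ddpcrTranslocationFrequency(x$n, x$k_fam, x$k_hex)
  }, numeric(1L))
  sd_small <- sd(est(2000, 1:40))
  sd_large <- sd(est(50000, 1:40))
  expect_lt(sd_large, sd_small)
})
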