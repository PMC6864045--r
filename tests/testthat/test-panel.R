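test_that("directed translocation junctions follow k(k-1)", {
  four <- enumerateTranslocations(c("TRAC", "B2M", "PDCD1", "PDCD1_OT"))
  expect_equal(nrow(four), 12L)
  expect_true(all(four$partner_a != four$partner_b))
  ## both orientations of every pair are present and distinct
  expect_equal(anyDuplicated(four[, c("partner_a", "partner_b")]), 0L)
  expect_equal(nrow(enumerateTranslocations(paste0("L", 1:10))), 90L)
  expect_equal(nrow(enumerateTranslocations("solo")), 0L)
  expect_equal(nrow(enumerateTranslocations(character())), 0L)
  expect_error(enumerateTranslocations(c("A", "A")), "duplicate")
  expect_error(panelLoci(c("A", "A")), "duplicate")

  ## equality with a brute-force double loop, under relabeling
  labs <- c("z9", "m1", "a7", "q2", "b4")
  got <- enumerateTranslocations(labs)
  want <- list()
  for (a in labs) for (b in labs) if (a != b)
    want[[length(want) + 1L]] <- c(a, b)
  want <- do.call(rbind, want)
  expect_setequal(paste(got$partner_a, got$partner_b),
                  paste(want[, 1L], want[, 2L]))
})

test_that("knockout-combination fractions decompose per-cell calls", {
  m <- matrix(c(TRUE, TRUE, TRUE,
                TRUE, TRUE, FALSE,
                TRUE, FALSE, FALSE,
                FALSE, FALSE, FALSE),
              nrow = 4L, byrow = TRUE,
              dimnames = list(NULL, c("TRAC", "B2M", "PDCD1")))
  res <- koCombinationFractions(m)
  expect_equal(res$by_count$fraction, rep(0.25, 4L))
  expect_equal(sum(res$combinations$fraction), 1)
  expect_equal(sum(res$by_count$fraction), 1)
  expect_equal(res$combinations$fraction[res$combinations$category == "WT"],
               0.25)

  ## all-knockout population
  all3 <- matrix(TRUE, 10L, 3L, dimnames = list(NULL, c("a", "b", "c")))
  r3 <- koCombinationFractions(all3)
  expect_equal(r3$by_count$fraction[r3$by_count$n_ko == 3L], 1)

  ## one-gene degenerate case reduces to a simple KO frequency
  one <- matrix(c(TRUE, FALSE, TRUE, TRUE), ncol = 1L,
                dimnames = list(NULL, "g"))
  r1 <- koCombinationFractions(one)
  expect_equal(r1$by_count$fraction[r1$by_count$n_ko == 1L], 0.75)

  expect_error(koCombinationFractions(matrix(logical(), 0L, 3L)), "empty")
})

test_that("independence benchmark matches closed-form products", {
  e <- expectedCombinationFractions(c(a = 1, b = 1, c = 1))
  expect_equal(e$by_count$fraction[e$by_count$n_ko == 3L], 1)
  e5 <- expectedCombinationFractions(c(a = .5, b = .5, c = .5))
  expect_equal(e5$combinations$fraction, rep(0.125, 8L))
  e9 <- expectedCombinationFractions(c(a = .9, b = .9, c = .9))
  expect_equal(e9$by_count$fraction[e9$by_count$n_ko == 3L], 0.729)
  expect_equal(sum(e9$combinations$fraction), 1)
  expect_equal(sum(e9$by_count$fraction), 1)
  ## marginals recover the input rates
  rates <- c(x = 0.2, y = 0.65, z = 0.9)
  er <- expectedCombinationFractions(rates)
  for (g in names(rates))
    expect_equal(sum(er$combinations$fraction[er$combinations[[g]]]),
                 unname(rates[g]))
  expect_error(expectedCombinationFractions(c(0.5, 1.2)), "\\[0, 1\\]")
})
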