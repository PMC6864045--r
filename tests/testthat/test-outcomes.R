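test_that("outcome enumeration is exhaustive and duplicate-free", {
  toy <- toyDonorLocus()
  g <- findSpliceGuides(toy$tm, toy$genome)   # one window C
  out <- enumerateOutcomes(g)
  expect_equal(nrow(out), 4L)
  expect_equal(anyDuplicated(out$assignment), 0L)
  ## sense junction dinucleotide across the four outcomes: GT, AT, TT, CT
  cls <- classifyOutcomes(out, g, toy$tm, toy$genome)
  junc <- substr(cls$sense_local, 15L, 16L)
  expect_setequal(junc, c("GT", "AT", "TT", "CT"))

  ## 4^m scaling and the combinatorial guard
  g2 <- g; mcols(g2)$window_cs <- "4,6"
  expect_equal(nrow(enumerateOutcomes(g2)), 16L)
  g0 <- g; mcols(g0)$window_cs <- ""
  out0 <- enumerateOutcomes(g0)
  expect_equal(nrow(out0), 1L)
  expect_equal(out0$assignment, "")
  g9 <- g; mcols(g9)$window_cs <- paste(1:9, collapse = ",")
  expect_error(enumerateOutcomes(g9), "sampling")
})

test_that("any conversion of the critical C abolishes the splice site", {
  ## the all-outcomes completeness claim: target and nontarget edits alike
  r <- makeSyntheticLocus(seed = 81, nExons = 3, plantDonorGuides = 1L,
                          plantAcceptorGuides = 2L)
  guides <- r$guides
  for (i in seq_along(guides)) {
    g <- guides[i]
    out <- classifyOutcomes(enumerateOutcomes(g), g, r$tm, r$genome)
    crit <- as.integer(strsplit(mcols(g)$critical_pos, ",")[[1L]])
    hit <- vapply(out$assignment, function(a) {
      ed <- strsplit(a, ";")[[1L]]
      any(as.integer(sub("[TAG]$", "", ed)) %in% crit)
    }, logical(1L), USE.NAMES = FALSE)
    expected <- if (mcols(g)$class == "splice_donor") "splice_donor_lost"
                else "splice_acceptor_lost"
    expect_true(all(out$consequence[hit] == expected))
    ## and the all-unchanged outcome is inert
    expect_equal(out$consequence[out$assignment == ""], "none")
  }
})

test_that("pmSTOP outcomes translate to stop/missense/silent correctly", {
  r <- makeSyntheticLocus(seed = 82, plantDonorGuides = integer(),
                          plantPmstopCodons = "CAA")
  g <- r$guides[mcols(r$guides)$ref_codon == "CAA"][1L]
  out <- classifyOutcomes(enumerateOutcomes(g), g, r$tm, r$genome)
  crit <- mcols(g)$critical_pos
  expect_equal(out$consequence[out$assignment == paste0(crit, "T")], "pmstop")
  ## C -> G gives GAA (Glu), C -> A gives AAA (Lys): missense either way
  expect_equal(out$consequence[out$assignment == paste0(crit, "G")],
               "missense")
  expect_equal(out$consequence[out$assignment == paste0(crit, "A")],
               "missense")
  summ <- summarizeCandidate(g, out)
  if (mcols(g)$window_cs == crit) {
    expect_equal(summ$frac_knockout, 1 / 3)
    expect_equal(summ$frac_missense, 2 / 3)
  }
  expect_equal(summ$frac_knockout + summ$frac_missense + summ$frac_silent, 1)
})

test_that("candidate summaries aggregate knockout fractions", {
  r <- makeSyntheticLocus(seed = 83, nExons = 3, plantDonorGuides = 1L)
  g <- r$guides[1L]
  out <- classifyOutcomes(enumerateOutcomes(g), g, r$tm, r$genome)
  summ <- summarizeCandidate(g, out)
  ## splice-class candidates: every critical-edited outcome is knockout
  expect_equal(summ$frac_knockout, 1.0)
  ## zero window Cs -> empty summary with a warning
  g0 <- g; mcols(g0)$window_cs <- ""
  expect_warning(s0 <- summarizeCandidate(g0, out), "no window cytosines")
  expect_equal(nrow(s0), 0L)
})

test_that("acceptor guides into terminal or noncoding exons are flagged", {
  ## intron 2 acceptor feeds the last exon of a 3-exon gene
  r <- makeSyntheticLocus(seed = 84, nExons = 3, plantDonorGuides = integer(),
                          plantAcceptorGuides = 2L)
  g <- r$guides[mcols(r$guides)$class == "splice_acceptor"][1L]
  out <- classifyOutcomes(enumerateOutcomes(g), g, r$tm, r$genome)
  expect_true(all(grepl("noncoding_or_terminal_exon", out$flags) |
                  !mcols(g)$last_exon))
  ## nontarget-only outcomes are marked
  crit <- mcols(g)$critical_pos
  nt <- out[out$assignment == paste0(crit, "A"), ]
  expect_true(grepl("nontarget_only", nt$flags))
})
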