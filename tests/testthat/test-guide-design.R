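test_that("the worked toy donor locus yields its single hand-derived guide", {
  toy <- toyDonorLocus()
  g <- findSpliceGuides(toy$tm, toy$genome, baseEditorProfile())
  expect_length(g, 1L)
  expect_equal(mcols(g)$protospacer, "ACTTACTGTGAAGTCAGATC")
  expect_equal(mcols(g)$pam, "TGG")
  expect_equal(mcols(g)$critical_pos, "6")
  expect_equal(mcols(g)$strand_rel, "antisense")
  expect_equal(mcols(g)$class, "splice_donor")
  ## genomic footprint: core position 17 = padded position pad + 17
  expect_equal(BiocGenerics::start(g), 40L + 17L)
  expect_equal(as.character(BiocGenerics::strand(g)), "-")
})

test_that("destroying the PAM anchor removes the candidate", {
  toy <- toyDonorLocus()
  seqstr <- as.character(toy$genome[[1L]])
  ## the only CC on the sense strand anchors the antisense NGG
  substr(seqstr, 54L, 55L) <- "AA"   # core positions 14-15
  mut <- Biostrings::DNAStringSet(seqstr)
  names(mut) <- "toy"
  expect_length(findSpliceGuides(toy$tm, mut, baseEditorProfile()), 0L)
})

test_that("relaxing the PAM gives a superset of candidates", {
  r <- makeSyntheticLocus(seed = 41, nExons = 3, plantDonorGuides = 1L,
                          plantAcceptorGuides = 2L)
  ngg <- findSpliceGuides(r$tm, r$genome, baseEditorProfile(pam = "NGG"))
  ng <- findSpliceGuides(r$tm, r$genome, baseEditorProfile(pam = "NG"))
  key <- function(g) paste(mcols(g)$protospacer, mcols(g)$target)
  expect_true(all(key(ngg) %in% key(ng)))
  expect_gte(length(ng), length(ngg))
})

test_that("finder agrees with the brute-force both-strand oracle", {
  for (seed in c(51, 52, 53)) {
    r <- makeSyntheticLocus(seed = seed, nExons = 3, plantDonorGuides = 1L,
                            plantAcceptorGuides = 2L,
                            plantPmstopCodons = "CAA")
    inp <- o_inputs(r)
    got <- findSpliceGuides(r$tm, r$genome, baseEditorProfile())
    want <- oracle_splice(inp$seqstr, inp$exons, inp$strand)
    expect_identical(
      sort(paste(mcols(got)$class, mcols(got)$protospacer,
                 as.character(BiocGenerics::strand(got)),
                 BiocGenerics::start(got), sep = "|")),
      o_key_splice(want))
  }
})

test_that("widening the editing window never removes candidates", {
  r <- makeSyntheticLocus(seed = 54, nExons = 3, plantDonorGuides = 1L,
                          plantAcceptorGuides = 1L)
  narrow <- findSpliceGuides(r$tm, r$genome,
                             baseEditorProfile(windowStart = 5, windowEnd = 7))
  wide <- findSpliceGuides(r$tm, r$genome,
                           baseEditorProfile(windowStart = 4, windowEnd = 8))
  key <- function(g) paste(mcols(g)$protospacer, mcols(g)$target)
  expect_true(all(key(narrow) %in% key(wide)))
  ## every critical position lies inside the window used
  cp <- as.integer(mcols(wide)$critical_pos)
  expect_true(all(cp >= 4L & cp <= 8L))
})

test_that("strand-flipped fixtures design identical protospacers", {
  for (seed in c(55, 56)) {
    rp <- makeSyntheticLocus(seed = seed, plantDonorGuides = 1L,
                             plantAcceptorGuides = 2L,
                             plantPmstopCodons = c("CAA", "TGG"))
    rm <- makeSyntheticLocus(seed = seed, plantDonorGuides = 1L,
                             plantAcceptorGuides = 2L,
                             plantPmstopCodons = c("CAA", "TGG"),
                             strandOut = "-")
    expect_identical(sort(rp$truth_guides$protospacer),
                     sort(rm$truth_guides$protospacer))
    expect_identical(sort(paste(rp$truth_guides$class, rp$truth_guides$target)),
                     sort(paste(rm$truth_guides$class, rm$truth_guides$target)))
  }
})

test_that("candidates overlapping N bases are dropped", {
  ## plant an N run in the middle of intron 1 right where the acceptor-side
  ## scan would otherwise look; candidates must never contain N
  r <- makeSyntheticLocus(seed = 57, nExons = 3, plantDonorGuides = 1L,
                          plantAcceptorGuides = 1L, plantNRun = 1L)
  g <- findSpliceGuides(r$tm, r$genome)
  expect_false(any(grepl("N", mcols(g)$protospacer, fixed = TRUE)))
})
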