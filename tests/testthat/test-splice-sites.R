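test_that("every intron yields one donor and one acceptor", {
  r <- makeSyntheticLocus(seed = 31, nExons = 4)
  sites <- extractSpliceSites(r$tm, r$genome)
  expect_equal(length(sites), 2L * (4L - 1L))
  expect_equal(sum(sites$kind == "donor"), 3L)
  expect_equal(sum(sites$kind == "acceptor"), 3L)
  expect_true(all(sites$canonical))
  expect_true(all(sites$dinucleotide[sites$kind == "donor"] == "GT"))
  expect_true(all(sites$dinucleotide[sites$kind == "acceptor"] == "AG"))
  ## invariant: the sense base at critical_g is G for canonical sites
  for (i in seq_along(sites)) {
    b <- getGenomeSequence(r$genome, seqnames(r$tm),
                           sites$critical_g[i] - 1L, sites$critical_g[i],
                           strand = strand(r$tm))
    expect_equal(b, "G")
  }
})

test_that("single-exon transcripts and non-canonical sites are handled", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c", strrep("ACGT", 30)), fa)
  g <- readGenome(fa)
  single <- transcriptModel("t", "g",
    GenomicRanges::GRanges("c", IRanges::IRanges(1, 60), "+"))
  expect_length(extractSpliceSites(single, g), 0L)

  r <- makeSyntheticLocus(seed = 32, nExons = 3, noncanonicalDonor = 2L,
                          plantDonorGuides = 1L)
  sites <- extractSpliceSites(r$tm, r$genome)
  bad <- sites[sites$kind == "donor" & sites$intron_index == 2L]
  expect_false(bad$canonical)
  expect_equal(bad$dinucleotide, "GC")
  ## non-canonical sites are excluded from design by default
  guides <- findSpliceGuides(r$tm, r$genome)
  expect_false(any(mcols(guides)$intron_index == 2L))
})

test_that("splice windows are sense-strand and centered on the junction", {
  r <- makeSyntheticLocus(seed = 33, nExons = 3)
  sites <- extractSpliceSites(r$tm, r$genome)
  don <- sites[sites$kind == "donor"][1L]
  w <- spliceWindow(don, r$genome, flank = 30L)
  expect_equal(nchar(w$sequence), 62L)
  expect_equal(substr(w$sequence, 31L, 32L), "GT")  # 0-based flank..flank+1
  expect_error(spliceWindow(don, r$genome, flank = 19L), "flank")

  ## minus-strand window equals the hand reverse complement
  rm <- makeSyntheticLocus(seed = 33, nExons = 3, strandOut = "-")
  sm <- extractSpliceSites(rm$tm, rm$genome)
  dm <- sm[sm$kind == "donor" & sm$intron_index == 1L]
  wm <- spliceWindow(dm, rm$genome, flank = 30L)
  plus <- getGenomeSequence(rm$genome, as.character(seqnames(dm)),
                            wm$genomic_start,
                            wm$genomic_start + 62L)
  expect_identical(wm$sequence, o_revcomp(plus))
  expect_identical(wm$sequence, w$sequence)  # strand symmetry, same seed

  ## windows running off the contig are an error naming the site
  tiny <- toyDonorLocus(pad = 5L)
  s <- extractSpliceSites(tiny$tm, tiny$genome)
  expect_error(spliceWindow(s[1L], tiny$genome, flank = 30L),
               "truncated by contig end")
})

test_that("strand-flipped rendering mirrors site coordinates", {
  rp <- makeSyntheticLocus(seed = 34, nExons = 3)
  rm <- makeSyntheticLocus(seed = 34, nExons = 3, strandOut = "-")
  sp <- extractSpliceSites(rp$tm, rp$genome)
  sm <- extractSpliceSites(rm$tm, rm$genome)
  L <- length(rp$genome[[1L]])
  expect_equal(sm$dinucleotide, sp$dinucleotide)
  expect_equal(sm$canonical, sp$canonical)
  ## coordinates mirror: start' = L - end + 1
  expect_equal(BiocGenerics::start(sm), L - BiocGenerics::end(sp) + 1L)
})
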