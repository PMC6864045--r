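## Deterministic synthetic loci. A generated locus is a single-contig genome
## carrying one multi-exon transcript with canonical GT/AG introns, an ATG..
## stop CDS, and a configurable set of planted, window-compatible guide
## targets. Spacer sequence is random given the seed; after assembly the
## locus is "repaired": the guide finders are re-run and any candidate that
## was not planted has one free PAM base mutated, iterating to a fixpoint,
## so the planted truth table is exactly the designable guide set.

.SAFE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("CAA", "CAG", "CGA", "TGG",
                          "TAA", "TAG", "TGA"))

.rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' The worked toy donor locus
#'
#' A minimal hand-checkable fixture: a 45-nt core sequence whose single
#' canonical splice donor (intron \code{GTAAGT...}) admits exactly one
#' antisense NGG protospacer with the splice-critical C at editing-window
#' position 6. The core is embedded in poly-A padding so that extraction
#' windows fit on the contig; padding contributes no C and therefore no
#' additional PAM or candidate.
#'
#' @param pad Poly-A padding per side (default 40).
#' @return List with \code{genome} (\code{DNAStringSet}, contig
#'   \code{"toy"}), \code{tm} ([TranscriptModel-class]), and \code{core}
#'   (the unpadded 45-nt sequence).
#' @export
toyDonorLocus <- function(pad = 40L) {
  core <- "ATGGCTAGCAAATCCAGATCTGACTTCACAGTAAGTACACACACA"
  seq <- paste0(strrep("A", pad), core, strrep("A", pad))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "toy"
  ex1 <- c(pad + 1L, pad + 30L)          # core [1, 30]
  ex2 <- c(pad + 37L, pad + 45L)         # after 6-nt intron "GTAAGT"
  tm <- transcriptModel("TOY1", "TOYG", GRanges("toy",
    IRanges(start = c(ex1[1L], ex2[1L]), end = c(ex1[2L], ex2[2L])),
    strand = "+"))
  list(genome = genome, tm = tm, core = core)
}

## ---- synthetic locus ------------------------------------------------------

#' Generate a synthetic locus with planted guide targets
#'
#' Builds a single-transcript locus from a seed: exon/intron lengths are
#' drawn from the given ranges, introns are canonical GT..AG (optionally one
#' non-canonical GC donor), the CDS runs ATG .. stop across the exons, and
#' the requested guide targets are planted with window-compatible PAMs
#' (editing-window position 6 for the critical C). After assembly the locus
#' is deterministically repaired so that the guide finders recover the
#' planted candidates and nothing else. The same seed always produces
#' byte-identical files.
#'
#' @param seed Integer seed.
#' @param nExons Number of exons (>= 2).
#' @param exonLengthRange,intronLengthRange Length ranges (nt); minima of 60
#'   and 40 are enforced.
#' @param plantDonorGuides,plantAcceptorGuides Intron indices at which to
#'   plant a splice-disrupting guide (PAM anchor written into the sequence).
#' @param plantPmstopCodons Character vector of codon types to plant, from
#'   \code{CAA}, \code{CAG}, \code{CGA} (sense route) and \code{TGG}
#'   (antisense route).
#' @param noncanonicalDonor Intron index whose donor is written \code{GC}
#'   (recorded with \code{canonical = FALSE}; no guide planted), or 0.
#' @param plantNRun Intron index into whose center a 5-nt N run is written,
#'   or 0.
#' @param strandOut \code{"+"} or \code{"-"}: the minus rendering
#'   reverse-complements the contig and flips the annotation, leaving the
#'   designable protospacers identical.
#' @param utr5,utr3 Untranslated leader/trailer lengths within the first and
#'   last exon.
#' @param margin Plain sequence before/after the gene on the contig.
#' @param profile [BaseEditorProfile-class] used for planting and repair.
#' @param flank Splice window flank used during repair (default 30).
#' @param dir Output directory; when non-\code{NULL}, FASTA, GTF, GFF3 and
#'   truth TSVs are written there.
#' @param prefix File name prefix (default \code{"locus"}).
#' @return List with \code{genome}, \code{tm}, \code{sites} (splice-site
#'   \code{GRanges}), \code{guides} (the designable [GuideSet-class] ==
#'   planted truth), \code{truth_guides} (\code{data.frame}),
#'   \code{truth_sites} (\code{data.frame}), and \code{files} (named paths,
#'   when written).
#' @export
makeSyntheticLocus <- function(seed, nExons = 3L,
                               exonLengthRange = c(80L, 140L),
                               intronLengthRange = c(60L, 120L),
                               plantDonorGuides = 1L,
                               plantAcceptorGuides = integer(),
                               plantPmstopCodons = character(),
                               noncanonicalDonor = 0L,
                               plantNRun = 0L,
                               strandOut = "+",
                               utr5 = 30L, utr3 = 30L, margin = 60L,
                               profile = baseEditorProfile(),
                               flank = 30L,
                               dir = NULL, prefix = "locus") {
  stopifnot(nExons >= 2L, strandOut %in% c("+", "-"))
  exonLengthRange <- pmax(as.integer(exonLengthRange), 60L)
  intronLengthRange <- pmax(as.integer(intronLengthRange), 40L)
  bad_pm <- setdiff(plantPmstopCodons, c(.PMSTOP_SENSE, "TGG"))
  if (length(bad_pm))
    stop("unknown pmSTOP codon type(s): ", paste(bad_pm, collapse = ", "))
  if (any(c(plantDonorGuides, plantAcceptorGuides) > nExons - 1L))
    stop("planted intron index exceeds intron count")

  res <- .with_seed(seed, {
    exon_len <- sample(seq(exonLengthRange[1L], exonLengthRange[2L]),
                       nExons, replace = TRUE)
    intron_len <- sample(seq(intronLengthRange[1L], intronLengthRange[2L]),
                         nExons - 1L, replace = TRUE)
    .build_locus(seed, exon_len, intron_len, plantDonorGuides,
                 plantAcceptorGuides, plantPmstopCodons,
                 as.integer(noncanonicalDonor), as.integer(plantNRun),
                 utr5, utr3, margin, profile, flank)
  })

  if (strandOut == "-") res <- .flip_locus(res, profile, flank)

  sites <- extractSpliceSites(res$tm, res$genome)
  guides <- .scan_all_guides(res$tm, res$genome, profile, flank)
  if (length(guides) != nrow(res$plant))
    stop("internal error: designable guides do not match the planted set")
  truth_guides <- data.frame(
    class = mcols(guides)$class, target = mcols(guides)$target,
    protospacer = mcols(guides)$protospacer, pam = mcols(guides)$pam,
    strand_rel = mcols(guides)$strand_rel,
    contig = as.character(seqnames(guides)),
    start0 = start(guides) - 1L, end0 = end(guides),
    genomic_strand = as.character(strand(guides)),
    critical_pos = mcols(guides)$critical_pos, stringsAsFactors = FALSE)
  truth_sites <- data.frame(
    transcript = sites$transcript_id, kind = sites$kind,
    intron_index = sites$intron_index,
    contig = as.character(seqnames(sites)),
    start0 = start(sites) - 1L, end0 = end(sites),
    dinucleotide = sites$dinucleotide, canonical = sites$canonical,
    stringsAsFactors = FALSE)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- .write_locus(res, sites, truth_guides, dir, prefix)
  }
  list(genome = res$genome, tm = res$tm, sites = sites, guides = guides,
       truth_guides = truth_guides, truth_sites = truth_sites,
       plant = res$plant, strand = res$strand, files = files)
}

.build_locus <- function(seed, exon_len, intron_len, plant_don, plant_acc,
                         plant_pm, noncanon, n_run, utr5, utr3, margin,
                         profile, flank) {
  nEx <- length(exon_len)
  S <- sum(exon_len)
  cds_len <- S - utr5 - utr3
  cds_len <- cds_len - (cds_len %% 3L)
  if (cds_len < 60L)
    stop("infeasible locus spec: spliced transcript too short for a CDS")
  utr3_eff <- S - utr5 - cds_len

  ## genomic layout (sense space, plus strand, 1-based)
  starts <- integer(nEx); ends <- integer(nEx)
  pos <- margin + 1L
  for (i in seq_len(nEx)) {
    starts[i] <- pos; ends[i] <- pos + exon_len[i] - 1L
    pos <- ends[i] + 1L + if (i < nEx) intron_len[i] else 0L
  }
  clen <- ends[nEx] + margin
  cum <- cumsum(exon_len) - exon_len  # spliced bases before each exon

  spliced_to_genomic <- function(s) {
    e <- findInterval(s - 1L, cumsum(exon_len), left.open = FALSE) + 1L
    starts[e] + (s - cum[e]) - 1L
  }

  ## base sequence
  bases <- .rand_bases(clen)
  n_codons <- cds_len %/% 3L
  codon_stream <- c("ATG",
                    sample(.SAFE_CODONS, n_codons - 2L, replace = TRUE),
                    "TAA")
  spliced <- c(.rand_bases(utr5),
               strsplit(paste(codon_stream, collapse = ""), "")[[1L]],
               .rand_bases(utr3_eff))
  for (s in seq_len(S)) bases[spliced_to_genomic(s)] <- spliced[s]

  ## canonical (or planted non-canonical) splice dinucleotides
  protected <- logical(clen)
  for (i in seq_len(nEx - 1L)) {
    ds <- ends[i] + 1L
    de <- starts[i + 1L] - 1L
    don <- if (i == noncanon) c("G", "C") else c("G", "T")
    bases[ds:(ds + 1L)] <- don
    bases[(de - 1L):de] <- c("A", "G")
    protected[ds:(ds + 1L)] <- TRUE
    protected[(de - 1L):de] <- TRUE
  }

  plant <- data.frame(class = character(), target = character(),
                      proto_lo = integer(), stringsAsFactors = FALSE)
  plant_span <- function(lo, hi) protected[lo:hi] <<- TRUE

  forbidden <- c(.PMSTOP_SENSE, "TGG", .stop_codons)
  in_cds_codon <- function(g) {
    s <- NA_integer_
    for (e in seq_along(starts)) {
      if (g >= starts[e] && g <= ends[e]) {
        s <- cum[e] + g - starts[e] + 1L
        break
      }
    }
    if (is.na(s) || s <= utr5 || s > utr5 + n_codons * 3L)
      return(NULL)
    k <- (s - utr5 - 1L) %/% 3L + 1L
    list(k = k, pos = (s - utr5 - 1L) %% 3L + 1L,
         span = vapply(utr5 + 3L * (k - 1L) + 1:3, spliced_to_genomic,
                       integer(1L)))
  }

  ## a written anchor can turn an overlapped CDS codon into a pmSTOP-editable
  ## (or stop) codon right where bases will be protected; rewrite one free
  ## base of such codons, avoiding new CC/GG dinucleotides
  sanitize_anchor <- function(anchor) {
    for (g in anchor) {
      ci <- in_cds_codon(g)
      if (is.null(ci)) next
      if (!(paste(bases[ci$span], collapse = "") %in% forbidden)) next
      for (gp in setdiff(ci$span, anchor)) {
        if (protected[gp]) next
        cur <- bases[gp]
        done <- FALSE
        for (b in setdiff(c("T", "A", "C", "G"), cur)) {
          bases[gp] <<- b
          cod <- paste(bases[ci$span], collapse = "")
          pair_ok <- !any(c(paste0(bases[gp - 1L], b), paste0(b, bases[gp + 1L]))
                          %in% c("CC", "GG"))
          if (!(cod %in% forbidden) && pair_ok) { done <- TRUE; break }
          bases[gp] <<- cur
        }
        if (done) break
      }
    }
  }

  ## splice guides: PAM anchor "CCA" upstream of the protospacer span so the
  ## critical C sits at editing-window position 6
  for (i in plant_don) {
    g <- ends[i] + 1L
    bases[(g - 17L):(g - 15L)] <- c("C", "C", "A")
    sanitize_anchor((g - 17L):(g - 15L))
    plant_span(g - 17L, g + 5L)
    plant <- rbind(plant, data.frame(class = "splice_donor",
                                     target = paste0("donor_intron", i),
                                     proto_lo = g - 14L))
  }
  for (i in plant_acc) {
    g <- starts[i + 1L] - 1L
    bases[(g - 17L):(g - 15L)] <- c("C", "C", "A")
    plant_span(g - 17L, g + 5L)
    ## acceptor protospacer tail reaches 5 nt into the downstream exon
    sanitize_anchor((g + 1L):(g + 5L))
    plant <- rbind(plant, data.frame(class = "splice_acceptor",
                                     target = paste0("acceptor_intron", i),
                                     proto_lo = g - 14L))
  }

  ## pmSTOP codons: placed on a same-exon stretch, clear of the exon edges
  ## (so planted PAM anchors cannot collide with splice-guide regions)
  if (length(plant_pm)) {
    cumhi <- cumsum(exon_len)
    ok_codon <- vapply(seq_len(n_codons), function(k) {
      if (k < 9L || k > n_codons - 9L) return(FALSE)
      s1 <- utr5 + 3L * (k - 1L) + 1L
      e <- findInterval(s1 - 1L, cumhi) + 1L
      s1 - 18L >= cum[e] + 1L + 6L && s1 + 20L <= cumhi[e] - 21L
    }, logical(1L))
    slots <- which(ok_codon)
    ## codon footprint touched by a plant (1-codon buffer included)
    footprint <- function(type, k)
      if (type == "TGG") c(k - 7L, k + 3L) else c(k - 3L, k + 7L)
    picked <- list()
    ## TGG footprints extend left, sense footprints right: planting TGG
    ## first packs both kinds into a tight slot run
    for (type in plant_pm[order(plant_pm != "TGG")]) {
      free <- slots[vapply(slots, function(k) {
        fp <- footprint(type, k)
        all(vapply(picked, function(pr)
          fp[2L] < pr[1L] || fp[1L] > pr[2L], logical(1L)))
      }, logical(1L))]
      if (!length(free))
        stop("infeasible locus spec: no room to plant pmSTOP codon ", type)
      k <- free[1L]
      picked <- c(picked, list(footprint(type, k)))
      set_codon <- function(kk, seq3) {
        for (j in 1:3) {
          g <- spliced_to_genomic(utr5 + 3L * (kk - 1L) + j)
          bases[g] <<- substr(seq3, j, j)
        }
      }
      g1 <- spliced_to_genomic(utr5 + 3L * (k - 1L) + 1L)
      set_codon(k, type)
      if (type == "TGG") {
        set_codon(k - 6L, "ATC")  # ..C completes the CC PAM anchor;
        set_codon(k - 5L, "CTT")  # pos2 != C avoids a second anchor

        plant_span(g1 - 16L, g1 + 6L)
        plant <- rbind(plant, data.frame(class = "pmstop",
                                         target = paste0("codon", k),
                                         proto_lo = g1 - 13L))
      } else {
        set_codon(k + 5L, "AGG")
        plant_span(g1 - 5L, g1 + 17L)
        plant <- rbind(plant, data.frame(class = "pmstop",
                                         target = paste0("codon", k),
                                         proto_lo = g1 - 5L))
      }
    }
  }

  if (n_run > 0L) {
    mid <- (ends[n_run] + 1L + starts[n_run + 1L] - 1L) %/% 2L
    bases[(mid - 2L):(mid + 2L)] <- "N"
    plant_span(mid - 2L, mid + 2L)
  }

  ## repair to fixpoint: destroy the PAM of every unplanned candidate
  mk_state <- function() {
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- paste0("synth", seed)
    cds_g <- vapply((utr5 + 1L):(utr5 + length(codon_stream) * 3L),
                    spliced_to_genomic, integer(1L))
    cds_iv <- .runs_to_ranges(sort(cds_g))
    tm <- transcriptModel(paste0("SYNT", seed), paste0("SYNG", seed),
      GRanges(names(genome), IRanges(start = starts, end = ends),
              strand = "+"),
      GRanges(names(genome), IRanges(start = cds_iv$lo, end = cds_iv$hi),
              strand = "+"))
    list(genome = genome, tm = tm)
  }
  pat <- strsplit(pamPattern(profile), "", fixed = TRUE)[[1L]]
  for (round in seq_len(25L)) {
    st <- mk_state()
    found <- rbind(
      .find_splice_records(st$tm, st$genome, profile, flank),
      .find_pmstop_records(st$tm, st$genome, profile))
    planted_hit <- logical(nrow(found))
    for (q in seq_len(nrow(plant)))
      planted_hit <- planted_hit |
        (found$class == plant$class[q] &
         found$target == plant$target[q] &
         found$proto_lo == plant$proto_lo[q])
    unplanned <- which(!planted_hit)
    if (!length(unplanned)) {
      if (sum(planted_hit) < nrow(plant))
        stop("infeasible locus spec: a planted guide was not recovered")
      return(list(genome = st$genome, tm = st$tm, plant = plant,
                  strand = "+"))
    }
    for (u in unplanned) {
      gd <- found[u, ]
      pl <- nchar(gd$pam)
      pam_plus <- if (gd$gstrand == "+")
        gd$proto_hi + seq_len(pl) else gd$proto_lo - seq_len(pl)
      fixed_pos <- pam_plus[pat != "N"]
      ## an earlier repair in this round may already have destroyed this
      ## candidate's PAM; re-read it from the current sequence
      cur_pam <- if (gd$gstrand == "+")
        paste(bases[pam_plus], collapse = "")
      else paste(.complement_base(bases[pam_plus]), collapse = "")
      if (!.iupac_match(cur_pam, pamPattern(profile))) next
      repaired <- FALSE
      for (gp in fixed_pos) {
        if (protected[gp]) next
        cur <- bases[gp]
        for (b in setdiff(c("A", "T", "G", "C"), cur)) {
          old <- bases[gp]; bases[gp] <- b
          ci <- in_cds_codon(gp)
          ok <- !any(c(paste0(bases[gp - 1L], b), paste0(b, bases[gp + 1L]))
                     %in% c("CC", "GG"))
          if (ok && !is.null(ci)) {
            new_codon <- paste(bases[ci$span], collapse = "")
            if (new_codon %in% forbidden || ci$k == 1L) ok <- FALSE
          }
          if (ok) { repaired <- TRUE; break }
          bases[gp] <- old
        }
        if (repaired) break
      }
      if (!repaired && gd$class == "pmstop") {
        ## fallback: destroy the target codon instead of the PAM
        k <- gd$codon_index
        span <- vapply(utr5 + 3L * (k - 1L) + 1:3, spliced_to_genomic,
                       integer(1L))
        for (j in which(!protected[span])) {
          cur <- bases[span[j]]
          for (b in setdiff(c("A", "T", "G", "C"), cur)) {
            bases[span[j]] <- b
            if (!(paste(bases[span], collapse = "") %in% forbidden)) {
              repaired <- TRUE; break
            }
            bases[span[j]] <- cur
          }
          if (repaired) break
        }
      }
      if (!repaired)
        stop("infeasible locus spec: cannot repair unplanned candidate ",
             gd$class, " ", gd$target, " at ", gd$proto_lo,
             " (", gd$protospacer, ") without touching planted bases")
    }
  }
  stop("infeasible locus spec: repair did not converge")
}

.runs_to_ranges <- function(x) {
  br <- c(0L, which(diff(x) != 1L), length(x))
  data.frame(lo = x[br[-length(br)] + 1L], hi = x[br[-1L]])
}

.scan_all_guides <- function(tm, genome, profile, flank) {
  g1 <- findSpliceGuides(tm, genome, profile, flank)
  g2 <- findPmstopGuides(tm, genome, profile)
  new("GuideSet", c(as(g1, "GRanges"), as(g2, "GRanges")))
}

.flip_locus <- function(res, profile, flank) {
  L <- length(res$genome[[1L]])
  contig <- names(res$genome)
  genome <- Biostrings::DNAStringSet(reverseComplement0(
    as.character(res$genome[[1L]])))
  names(genome) <- contig
  flip <- function(gr, strand_new) {
    GRanges(contig, IRanges(start = L - end(gr) + 1L,
                            end = L - start(gr) + 1L), strand = strand_new)
  }
  tm <- transcriptModel(res$tm@transcriptId, res$tm@geneId,
                        flip(res$tm@exons, "-"), flip(res$tm@cds, "-"))
  plant <- res$plant
  plant$proto_lo <- L - (plant$proto_lo + 19L) + 1L
  list(genome = genome, tm = tm, plant = plant, strand = "-")
}

.write_locus <- function(res, sites, truth_guides, dir, prefix) {
  tm <- res$tm; genome <- res$genome
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gtf <- file.path(dir, paste0(prefix, ".gtf"))
  gff3 <- file.path(dir, paste0(prefix, ".gff3"))
  sites_tsv <- file.path(dir, paste0(prefix, "_truth_sites.tsv"))
  guides_tsv <- file.path(dir, paste0(prefix, "_truth_guides.tsv"))
  writeGenome(genome, fa)
  .write_annotation(tm, gtf, "gtf")
  .write_annotation(tm, gff3, "gff3")
  writeSpliceSiteTable(sites, sites_tsv)
  .write_tsv(truth_guides, guides_tsv)
  c(fasta = fa, gtf = gtf, gff3 = gff3, truth_sites = sites_tsv,
    truth_guides = guides_tsv)
}

.write_annotation <- function(tm, path, format = c("gtf", "gff3")) {
  format <- match.arg(format)
  contig <- seqnames(tm)
  st <- strand(tm)
  ex <- tm@exons; cd <- tm@cds
  gl <- range(c(start(ex), end(ex), start(cd), end(cd)))
  ## CDS phase per interval (bases to skip before the first complete codon)
  phase <- integer(length(cd))
  if (length(cd)) {
    before <- cumsum(width(cd)) - width(cd)
    phase <- (3L - before %% 3L) %% 3L
  }
  lines <- character()
  add <- function(feature, lo, hi, frame, attr) {
    lines <<- c(lines, paste(contig, "spliceCBE", feature, lo, hi, ".",
                             st, frame, attr, sep = "\t"))
  }
  tid <- tm@transcriptId; gid <- tm@geneId
  if (format == "gtf") {
    at <- function(extra = "")
      paste0("gene_id \"", gid, "\"; transcript_id \"", tid, "\";", extra)
    add("gene", gl[1L], gl[2L], ".",
        paste0("gene_id \"", gid, "\";"))
    add("transcript", gl[1L], gl[2L], ".", at())
    for (i in seq_along(ex))
      add("exon", start(ex)[i], end(ex)[i], ".",
          at(paste0(" exon_number \"", i, "\";")))
    for (i in seq_along(cd))
      add("CDS", start(cd)[i], end(cd)[i], phase[i], at())
  } else {
    lines <- "##gff-version 3"
    add("gene", gl[1L], gl[2L], ".", paste0("ID=gene:", gid))
    add("mRNA", gl[1L], gl[2L], ".",
        paste0("ID=transcript:", tid, ";Parent=gene:", gid))
    for (i in seq_along(ex))
      add("exon", start(ex)[i], end(ex)[i], ".",
          paste0("ID=exon:", tid, ".", i, ";Parent=transcript:", tid))
    for (i in seq_along(cd))
      add("CDS", start(cd)[i], end(cd)[i], phase[i],
          paste0("ID=cds:", tid, ".", i, ";Parent=transcript:", tid))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
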