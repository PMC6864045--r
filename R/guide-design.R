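## Guide discovery. Protospacer coordinates follow the base-editing
## convention throughout: position 1 is the PAM-distal 5' base of the 20-nt
## protospacer; the PAM sits immediately 3' of position 20 on the same
## strand. A candidate is only emitted when the knockout-critical cytosine
## falls inside the editor's deamination window.

.guide_extra_mcols <- c("tx_strand", "kind", "intron_index", "critical_g",
                        "junction_lo", "dinucleotide", "last_exon",
                        "downstream_exon_coding", "downstream_exon_len",
                        "codon_index", "ref_codon")

.empty_guide_records <- function() {
  data.frame(contig = character(), proto_lo = integer(), proto_hi = integer(),
             gstrand = character(), protospacer = character(),
             pam = character(), strand_rel = character(), class = character(),
             target = character(), critical_pos = character(),
             window_cs = character(), spliced_offset = integer(),
             tx_strand = character(), kind = character(),
             intron_index = integer(), critical_g = integer(),
             junction_lo = integer(), dinucleotide = character(),
             last_exon = logical(), downstream_exon_coding = logical(),
             downstream_exon_len = integer(), codon_index = integer(),
             ref_codon = character(), stringsAsFactors = FALSE)
}

.records_to_guideset <- function(rec, transcript_id) {
  if (nrow(rec) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(id = character(), transcript_id = character(),
                           class = character(), protospacer = character(),
                           pam = character(), strand_rel = character(),
                           target = character(), critical_pos = character(),
                           window_cs = character(),
                           spliced_offset = integer())
    for (col in .guide_extra_mcols) mcols(gr)[[col]] <- vector(
      mode = class(.empty_guide_records()[[col]]), length = 0L)
    return(new("GuideSet", gr))
  }
  gr <- GRanges(seqnames = rec$contig,
                ranges = IRanges(start = rec$proto_lo, end = rec$proto_hi),
                strand = rec$gstrand)
  mcols(gr) <- DataFrame(
    id = paste(rec$class, transcript_id, rec$target, rec$proto_lo,
               rec$gstrand, sep = ":"),
    transcript_id = transcript_id,
    class = rec$class, protospacer = rec$protospacer, pam = rec$pam,
    strand_rel = rec$strand_rel, target = rec$target,
    critical_pos = rec$critical_pos, window_cs = rec$window_cs,
    spliced_offset = rec$spliced_offset)
  for (col in .guide_extra_mcols) mcols(gr)[[col]] <- rec[[col]]
  new("GuideSet", gr)
}

## all protospacer positions in [ws, we] whose base is C
.window_cs_of <- function(proto, ws, we) {
  ch <- strsplit(proto, "", fixed = TRUE)[[1L]]
  which(ch == "C" & seq_along(ch) >= ws & seq_along(ch) <= we)
}

.pos_join <- function(x) paste(x, collapse = ",")
.pos_split <- function(x) {
  if (!nzchar(x)) integer() else as.integer(strsplit(x, ",")[[1L]])
}

#' Find splice-disrupting base-editor guides
#'
#' For every canonical splice site of the transcript, scans the antisense
#' strand of the sense-sequence window around the junction for 20-nt
#' protospacers adjacent to the profile's PAM whose editing window covers
#' the splice-critical cytosine (the antisense base paired with the
#' invariant G of the GT/AG dinucleotide). Candidates whose protospacer or
#' PAM overlaps an N base are dropped.
#'
#' @param tm A [TranscriptModel-class] with at least two exons.
#' @param genome A \code{DNAStringSet}.
#' @param profile A [BaseEditorProfile-class].
#' @param flank Window flank per side (>= 20; default 30).
#' @param includeNoncanonical Also design against non-GT/AG junctions
#'   (default \code{FALSE}).
#' @return A [GuideSet-class]; empty when the transcript has no (canonical)
#'   splice sites.
#' @examples
#' toy <- toyDonorLocus()
#' g <- findSpliceGuides(toy$tm, toy$genome, baseEditorProfile())
#' mcols(g)[, c("protospacer", "pam", "critical_pos")]
#' @export
findSpliceGuides <- function(tm, genome, profile = baseEditorProfile(),
                             flank = 30L, includeNoncanonical = FALSE) {
  .records_to_guideset(
    .find_splice_records(tm, genome, profile, flank, includeNoncanonical),
    tm@transcriptId)
}

.find_splice_records <- function(tm, genome, profile, flank = 30L,
                                 includeNoncanonical = FALSE) {
  flank <- as.integer(flank)
  if (flank < 20L)
    stop("flank must be >= 20 nt (protospacer + PAM must fit the window)")
  sites <- .splice_sites_df(tm, genome)
  if (!includeNoncanonical && nrow(sites))
    sites <- sites[sites$canonical, , drop = FALSE]
  recs <- list()
  if (!nrow(sites)) return(.empty_guide_records())

  pam <- pamPattern(profile)
  pl <- nchar(pam)
  win <- editingWindow(profile)
  ws <- win[["start"]]; we <- win[["end"]]
  tx_minus <- strand(tm) == "-"
  contig <- seqnames(tm)

  for (k in seq_len(nrow(sites))) {
    site <- sites[k, ]
    w <- .splice_window0(genome, contig, site$lo, tx_minus, flank,
                         paste(tm@transcriptId, site$kind, "intron",
                               site$intron_index))
    sense <- w$sequence
    L <- nchar(sense)
    anti <- reverseComplement0(sense)
    gidx0 <- if (site$kind == "donor") flank else flank + 1L  # 0-based, sense
    cidx0 <- L - 1L - gidx0                                   # 0-based, anti
    for (i0 in 0:(L - 20L - pl)) {
      p <- cidx0 - i0 + 1L
      if (p < ws || p > we) next
      proto <- substr(anti, i0 + 1L, i0 + 20L)
      pam_obs <- substr(anti, i0 + 21L, i0 + 20L + pl)
      if (grepl("N", proto, fixed = TRUE) ||
          grepl("N", pam_obs, fixed = TRUE)) next
      if (!.iupac_match(pam_obs, pam)) next
      if (substr(proto, p, p) != "C") next
      if (tx_minus) {
        lo <- w$plus_start + i0; hi <- lo + 19L; gstrand <- "+"
      } else {
        hi <- w$plus_end - i0; lo <- hi - 19L; gstrand <- "-"
      }
      recs[[length(recs) + 1L]] <- data.frame(
        contig = contig, proto_lo = lo, proto_hi = hi, gstrand = gstrand,
        protospacer = proto, pam = pam_obs, strand_rel = "antisense",
        class = if (site$kind == "donor") "splice_donor"
                else "splice_acceptor",
        target = paste0(site$kind, "_intron", site$intron_index),
        critical_pos = .pos_join(p),
        window_cs = .pos_join(.window_cs_of(proto, ws, we)),
        spliced_offset = site$spliced_offset,
        tx_strand = if (tx_minus) "-" else "+",
        kind = site$kind, intron_index = site$intron_index,
        critical_g = site$critical_g, junction_lo = site$lo,
        dinucleotide = site$dinucleotide, last_exon = site$last_exon,
        downstream_exon_coding = site$downstream_exon_coding,
        downstream_exon_len = site$downstream_exon_len,
        codon_index = NA_integer_, ref_codon = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs)) do.call(rbind, recs) else .empty_guide_records()
}

## codons a C->T edit can convert to a stop:
##   sense strand:    CAA->TAA, CAG->TAG, CGA->TGA (editable C = codon pos 1)
##   antisense route: TGG (Trp) -> TAG/TGA/TAA via the Cs paired with G2/G3
.PMSTOP_SENSE <- c("CAA", "CAG", "CGA")

#' Find premature-stop (pmSTOP) base-editor guides
#'
#' Scans the coding sequence for codons a window-positioned C-to-T edit can
#' convert to a stop: \code{CAA}, \code{CAG}, \code{CGA} targeted through
#' sense-strand protospacers (the codon's C in the editing window), and
#' \code{TGG} targeted through antisense protospacers (either or both
#' antisense Cs paired with the tryptophan Gs in the window). The CDS stop
#' codon is excluded; 3'-UTR sequence is never scanned.
#'
#' @inheritParams findSpliceGuides
#' @return A [GuideSet-class].
#' @export
findPmstopGuides <- function(tm, genome, profile = baseEditorProfile()) {
  .records_to_guideset(.find_pmstop_records(tm, genome, profile),
                       tm@transcriptId)
}

.find_pmstop_records <- function(tm, genome, profile) {
  if (!length(tm@cds))
    stop("transcript ", tm@transcriptId, " has no annotated CDS")
  map <- .cds_map(tm)  # errors when frame is broken
  codons <- .codon_table(tm, genome, map)
  last_codon <- max(codons$codon)
  if (codons$seq[codons$codon == last_codon] %in% .stop_codons)
    codons <- codons[codons$codon != last_codon, , drop = FALSE]

  pam <- pamPattern(profile)
  pl <- nchar(pam)
  win <- editingWindow(profile)
  ws <- win[["start"]]; we <- win[["end"]]
  tx_minus <- strand(tm) == "-"
  contig <- seqnames(tm)
  clen <- length(genome[[contig]])
  recs <- list()

  plus_sub <- function(lo, hi) .genome_sub0(genome, contig, lo - 1L, hi)

  add_rec <- function(lo, hi, gstrand, proto, pam_obs, criticals, codon_k,
                      ref_codon, g1) {
    recs[[length(recs) + 1L]] <<- data.frame(
      contig = contig, proto_lo = lo, proto_hi = hi, gstrand = gstrand,
      protospacer = proto, pam = pam_obs,
      strand_rel = if (gstrand == (if (tx_minus) "-" else "+"))
        "sense" else "antisense",
      class = "pmstop", target = paste0("codon", codon_k),
      critical_pos = .pos_join(sort(criticals)),
      window_cs = .pos_join(.window_cs_of(proto, ws, we)),
      spliced_offset = .spliced_offset(tm, g1),
      tx_strand = if (tx_minus) "-" else "+",
      kind = NA_character_, intron_index = NA_integer_,
      critical_g = NA_integer_, junction_lo = NA_integer_,
      dinucleotide = NA_character_, last_exon = NA,
      downstream_exon_coding = NA, downstream_exon_len = NA_integer_,
      codon_index = codon_k, ref_codon = ref_codon,
      stringsAsFactors = FALSE)
  }

  ok_span <- function(lo, hi) lo >= 1L && hi <= clen
  clean <- function(...) !any(grepl("N", c(...), fixed = TRUE))

  for (row in seq_len(nrow(codons))) {
    k <- codons$codon[row]
    cseq <- codons$seq[row]
    sub <- map[map$codon == k, , drop = FALSE]
    g1 <- sub$genomic[sub$codon_pos == 1L]
    if (cseq %in% .PMSTOP_SENSE) {
      ## sense-strand protospacer over the codon's first-position C
      for (p in ws:we) {
        if (tx_minus) {
          lo <- g1 - 20L + p; hi <- g1 + p - 1L
          pam_lo <- lo - pl; pam_hi <- lo - 1L
          if (!ok_span(pam_lo, hi)) next
          proto <- reverseComplement0(plus_sub(lo, hi))
          pam_obs <- reverseComplement0(plus_sub(pam_lo, pam_hi))
          gstrand <- "-"
        } else {
          lo <- g1 - p + 1L; hi <- g1 + 20L - p
          pam_lo <- hi + 1L; pam_hi <- hi + pl
          if (!ok_span(lo, pam_hi)) next
          proto <- plus_sub(lo, hi)
          pam_obs <- plus_sub(pam_lo, pam_hi)
          gstrand <- "+"
        }
        if (!clean(proto, pam_obs)) next
        if (!.iupac_match(pam_obs, pam)) next
        if (substr(proto, p, p) != "C") next
        add_rec(lo, hi, gstrand, proto, pam_obs, p, k, cseq, g1)
      }
    } else if (cseq == "TGG") {
      ## antisense protospacer over the C(s) paired with G2/G3
      gG <- sub$genomic[sub$codon_pos %in% c(2L, 3L)]
      if (tx_minus) {
        ## antisense = plus strand; paired Cs sit at the Gs' plus coords
        starts <- sort(unique(unlist(lapply(gG, function(g) g - (ws:we) + 1L))))
        for (b in starts) {
          lo <- b; hi <- b + 19L
          pam_lo <- hi + 1L; pam_hi <- hi + pl
          if (!ok_span(lo, pam_hi)) next
          criticals <- (gG - lo + 1L)
          criticals <- criticals[criticals >= ws & criticals <= we]
          if (!length(criticals)) next
          proto <- plus_sub(lo, hi)
          pam_obs <- plus_sub(pam_lo, pam_hi)
          gstrand <- "+"
          if (!clean(proto, pam_obs)) next
          if (!.iupac_match(pam_obs, pam)) next
          if (!all(substr(rep(proto, length(criticals)), criticals,
                          criticals) == "C")) next
          add_rec(lo, hi, gstrand, proto, pam_obs, criticals, k, cseq, g1)
        }
      } else {
        ## antisense = minus strand; protospacer plus span [a, a+19],
        ## protospacer position p sits at plus coordinate a + 20 - p
        starts <- sort(unique(unlist(lapply(gG, function(g) g - 20L + ws:we))))
        for (a in starts) {
          lo <- a; hi <- a + 19L
          pam_lo <- lo - pl; pam_hi <- lo - 1L
          if (!ok_span(pam_lo, hi)) next
          criticals <- (lo + 20L - gG)
          criticals <- criticals[criticals >= ws & criticals <= we]
          if (!length(criticals)) next
          proto <- reverseComplement0(plus_sub(lo, hi))
          pam_obs <- reverseComplement0(plus_sub(pam_lo, pam_hi))
          gstrand <- "-"
          if (!clean(proto, pam_obs)) next
          if (!.iupac_match(pam_obs, pam)) next
          if (!all(substr(rep(proto, length(criticals)), criticals,
                          criticals) == "C")) next
          add_rec(lo, hi, gstrand, proto, pam_obs, criticals, k, cseq, g1)
        }
      }
    }
  }
  if (length(recs)) do.call(rbind, recs) else .empty_guide_records()
}
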