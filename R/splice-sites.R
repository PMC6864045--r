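## splice-site extraction; the plain-data.frame core is shared by the
## exported GRanges interface and the (hot) guide-finder loop

## one row per site, transcript order (donor, acceptor per intron);
## `lo` = 1-based plus-strand start of the junction dinucleotide
.splice_sites_df <- function(tm, genome) {
  ex <- tm@exons
  n <- length(ex)
  if (n < 2L)
    return(data.frame(lo = integer(), kind = character(),
                      intron_index = integer(), dinucleotide = character(),
                      canonical = logical(), critical_g = integer(),
                      spliced_offset = integer(), downstream_exon = integer(),
                      downstream_exon_len = integer(),
                      downstream_exon_coding = logical(),
                      last_exon = logical(), stringsAsFactors = FALSE))
  contig <- seqnames(tm)
  minus <- strand(tm) == "-"
  cumlen <- cumsum(width(ex))
  rows <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    if (minus) {
      don_lo <- start(ex)[i] - 2L          # plus "AC", sense "GT"
      acc_lo <- end(ex)[i + 1L] + 1L       # plus "CT", sense "AG"
      don_g <- start(ex)[i] - 1L
      acc_g <- end(ex)[i + 1L] + 1L
    } else {
      don_lo <- end(ex)[i] + 1L
      acc_lo <- start(ex)[i + 1L] - 2L
      don_g <- end(ex)[i] + 1L
      acc_g <- start(ex)[i + 1L] - 1L
    }
    read_dinuc <- function(lo) {
      s <- .genome_sub0(genome, contig, lo - 1L, lo + 1L)
      if (minus) reverseComplement0(s) else s
    }
    don_seq <- read_dinuc(don_lo)
    acc_seq <- read_dinuc(acc_lo)
    coding <- length(tm@cds) > 0L &&
      any(start(tm@cds) <= end(ex)[i + 1L] &
          end(tm@cds) >= start(ex)[i + 1L])
    rows[[i]] <- data.frame(
      lo = c(don_lo, acc_lo),
      kind = c("donor", "acceptor"),
      intron_index = i,
      dinucleotide = c(don_seq, acc_seq),
      canonical = c(don_seq == "GT", acc_seq == "AG"),
      critical_g = c(don_g, acc_g),
      spliced_offset = cumlen[i],
      downstream_exon = i + 1L,
      downstream_exon_len = width(ex)[i + 1L],
      downstream_exon_coding = coding,
      last_exon = (i + 1L) == n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Extract splice sites from a transcript model
#'
#' Every intron of the transcript yields one donor (intron 5' end, canonical
#' sense dinucleotide \code{GT}) and one acceptor (intron 3' end, canonical
#' \code{AG}). The splice-critical cytosine of a site is the antisense base
#' paired with the invariant \code{G} (donor \code{GT:CA}, acceptor
#' \code{AG:TC}); converting it with a cytosine base editor abolishes the
#' site. Non-canonical junctions are retained with \code{canonical = FALSE}.
#'
#' @param tm A [TranscriptModel-class] with at least one exon.
#' @param genome A \code{DNAStringSet}.
#' @return A \code{GRanges} (width-2 junction dinucleotide ranges, transcript
#'   order: donor then acceptor per intron) with metadata columns
#'   \code{kind}, \code{transcript_id}, \code{intron_index},
#'   \code{dinucleotide} (read on the pre-mRNA sense strand),
#'   \code{canonical}, \code{critical_g} (1-based genomic coordinate of the
#'   invariant G; the critical C lies opposite), \code{spliced_offset}
#'   (0-based junction offset in the spliced transcript),
#'   \code{downstream_exon}, \code{downstream_exon_len},
#'   \code{downstream_exon_coding}, and \code{last_exon} (acceptor feeds the
#'   final exon). A single-exon transcript returns an empty \code{GRanges}.
#' @export
extractSpliceSites <- function(tm, genome) {
  d <- .splice_sites_df(tm, genome)
  contig <- seqnames(tm)
  gr <- GRanges(seqnames = rep(contig, nrow(d)),
                ranges = IRanges(start = d$lo, width = rep(2L, nrow(d))),
                strand = rep(strand(tm), nrow(d)))
  mcols(gr) <- DataFrame(
    kind = d$kind, transcript_id = rep(tm@transcriptId, nrow(d)),
    intron_index = d$intron_index, dinucleotide = d$dinucleotide,
    canonical = d$canonical, critical_g = d$critical_g,
    spliced_offset = d$spliced_offset, downstream_exon = d$downstream_exon,
    downstream_exon_len = d$downstream_exon_len,
    downstream_exon_coding = d$downstream_exon_coding,
    last_exon = d$last_exon)
  gr
}

## sense-strand window core: errors (naming the site) if truncated
.splice_window0 <- function(genome, contig, lo, minus, flank, label) {
  wlo <- lo - flank
  whi <- lo + 1L + flank
  if (wlo < 1L || whi > length(genome[[contig]]))
    stop("splice window truncated by contig end for ", label)
  s <- .genome_sub0(genome, contig, wlo - 1L, whi)
  list(sequence = if (minus) reverseComplement0(s) else s,
       genomic_start = wlo - 1L, plus_start = wlo, plus_end = whi)
}

#' Sense-strand window around a splice site
#'
#' Extracts \code{2*flank + 2} bases of pre-mRNA sense sequence centered on
#' the junction dinucleotide (0-based window indices \code{flank} and
#' \code{flank + 1} hold the dinucleotide). The minimum flank of 20 nt
#' guarantees that any 20-nt protospacer + PAM whose editing window can
#' cover the critical C lies entirely inside the window.
#'
#' @param site One element of the \code{GRanges} from [extractSpliceSites()].
#' @param genome A \code{DNAStringSet}.
#' @param flank Bases per side, \code{>= 20}; default 30.
#' @return A list with \code{sequence} (sense strand), \code{genomic_start}
#'   (0-based plus-strand start of the window), \code{plus_start},
#'   \code{plus_end} (1-based inclusive), and the \code{site} row.
#' @export
spliceWindow <- function(site, genome, flank = 30L) {
  stopifnot(is(site, "GRanges"), length(site) == 1L)
  flank <- as.integer(flank)
  if (flank < 20L)
    stop("flank must be >= 20 nt (protospacer + PAM must fit the window)")
  w <- .splice_window0(genome, as.character(seqnames(site)), start(site),
                       as.character(strand(site)) == "-", flank,
                       paste(site$transcript_id, site$kind, "intron",
                             site$intron_index))
  c(w, list(site = site))
}

#' Write a splice-site report as TSV
#'
#' One row per site: transcript, kind, intron index, contig, 0-based
#' coordinate of the junction dinucleotide, dinucleotide (sense strand),
#' canonical flag.
#'
#' @param sites \code{GRanges} from [extractSpliceSites()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSpliceSiteTable <- function(sites, path) {
  d <- data.frame(
    transcript = sites$transcript_id,
    kind = sites$kind,
    intron_index = sites$intron_index,
    contig = as.character(seqnames(sites)),
    start0 = start(sites) - 1L,
    end0 = end(sites),
    dinucleotide = sites$dinucleotide,
    canonical = sites$canonical,
    stringsAsFactors = FALSE)
  .write_tsv(d, path)
}
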