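#' Read transcript models from a GTF or GFF3 annotation
#'
#' Parses exon and CDS features into one [TranscriptModel-class] per
#' transcript id. GTF (attributes \code{gene_id}/\code{transcript_id}) and
#' GFF3 (\code{ID}/\code{Parent}) dialects are both supported; the format is
#' chosen from the file extension (\code{.gtf} vs \code{.gff}/\code{.gff3}).
#' Coordinates are converted from the formats' 1-based inclusive convention
#' into \code{GRanges}. Every exon must lie within a contig of \code{genome};
#' strands other than \code{+}/\code{-} are rejected.
#'
#' @param path Annotation file path.
#' @param genome A \code{DNAStringSet} from [readGenome()].
#' @return Named list of [TranscriptModel-class] objects, keyed by
#'   transcript id.
#' @export
readTranscripts <- function(path, genome) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  type <- as.character(gr$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]
  type <- type[keep]
  if (!length(gr)) stop("annotation contains no exon features: ", path)

  if (fmt == "gtf") {
    tx <- as.character(gr$transcript_id)
    gene <- as.character(gr$gene_id)
  } else {
    parent <- vapply(gr$Parent, function(p)
      if (length(p)) sub("^transcript:", "", p[[1L]]) else NA_character_,
      character(1L))
    tx <- parent
    ## map transcript -> gene through mRNA/transcript features
    full <- rtracklayer::import(path, format = fmt)
    tx_feats <- full[as.character(full$type) %in%
                       c("mRNA", "transcript", "ncRNA")]
    tx_ids <- sub("^transcript:", "", as.character(tx_feats$ID))
    tx_gene <- vapply(tx_feats$Parent, function(p)
      if (length(p)) sub("^gene:", "", p[[1L]]) else NA_character_,
      character(1L))
    gene_map <- stats::setNames(tx_gene, tx_ids)
    gene <- unname(gene_map[tx])
    gene[is.na(gene)] <- tx[is.na(gene)]
  }
  if (anyNA(tx)) stop("exon/CDS feature without a transcript id in ", path)

  bad_strand <- !as.character(strand(gr)) %in% c("+", "-")
  if (any(bad_strand)) stop("unknown strand symbol in annotation: ", path)

  models <- lapply(split(seq_along(gr), tx), function(idx) {
    sub <- gr[idx]
    stype <- type[idx]
    ex <- granges(sub[stype == "exon"])
    cd <- granges(sub[stype == "CDS"])
    contig <- as.character(seqnames(ex))[1L]
    if (!contig %in% names(genome))
      stop("annotation references unknown contig '", contig, "'")
    if (any(end(ex) > length(genome[[contig]])) ||
        any(start(ex) < 1L))
      stop("exon outside contig bounds on '", contig, "'")
    transcriptModel(transcriptId = tx[idx][1L], geneId = gene[idx][1L],
                    exons = ex, cds = cd)
  })
  models[order(names(models))]
}

#' @rdname splicedSequence
#' @export
setMethod("splicedSequence", signature("TranscriptModel", "DNAStringSet"),
  function(x, genome) {
    contig <- seqnames(x)
    pieces <- vapply(seq_along(x@exons), function(i) {
      .genome_sub0(genome, contig, start(x@exons)[i] - 1L, end(x@exons)[i])
    }, character(1L))
    s <- paste(pieces[order(start(x@exons))], collapse = "")
    if (strand(x) == "-") s <- reverseComplement0(s)
    Biostrings::DNAString(s)
  })

## genomic coordinates (1-based) of every CDS base in transcript orientation,
## plus the codon index / in-codon position of each; NULL if no CDS
.cds_map <- function(tm) {
  if (!length(tm@cds)) return(NULL)
  minus <- strand(tm) == "-"
  pos <- unlist(lapply(seq_along(tm@cds), function(i) {
    p <- start(tm@cds)[i]:end(tm@cds)[i]
    if (minus) rev(p) else p
  }))
  n <- length(pos)
  if (n %% 3L != 0L)
    stop("CDS length (", n, ") of ", tm@transcriptId,
         " is not divisible by 3")
  data.frame(genomic = pos,
             cds_pos = seq_len(n),
             codon = (seq_len(n) - 1L) %/% 3L + 1L,
             codon_pos = (seq_len(n) - 1L) %% 3L + 1L)
}

## sense-strand codon sequences from a .cds_map
.codon_table <- function(tm, genome, map = .cds_map(tm)) {
  if (is.null(map)) return(NULL)
  contig <- seqnames(tm)
  minus <- strand(tm) == "-"
  pieces <- vapply(seq_along(tm@cds), function(i) {
    s <- .genome_sub0(genome, contig, start(tm@cds)[i] - 1L,
                      end(tm@cds)[i])
    if (minus) reverseComplement0(s) else s
  }, character(1L))
  cds_seq <- paste(pieces, collapse = "")
  n <- nchar(cds_seq)
  starts <- seq.int(1L, n, by = 3L)
  data.frame(codon = seq_along(starts),
             seq = substring(cds_seq, starts, starts + 2L))
}

## 0-based offset within the spliced transcript of a genomic position that
## falls inside an exon; junction offsets use the boundary convention
## offset = bases of spliced transcript upstream of the junction
.spliced_offset <- function(tm, genomic_pos) {
  ex <- tm@exons
  minus <- strand(tm) == "-"
  cum <- cumsum(width(ex)) - width(ex)
  for (i in seq_along(ex)) {
    if (genomic_pos >= start(ex)[i] && genomic_pos <= end(ex)[i]) {
      within <- if (minus) end(ex)[i] - genomic_pos
                else genomic_pos - start(ex)[i]
      return(cum[i] + within)
    }
  }
  NA_integer_
}
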