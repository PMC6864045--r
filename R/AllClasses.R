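#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics strand start end width
NULL

#' Base editor profile
#'
#' Describes the targeting chemistry of a cytosine base editor: the PAM it
#' requires (IUPAC string, matched 3' of the protospacer on the targeted
#' strand) and the protospacer positions of its efficient deamination window.
#' Position 1 is the PAM-distal 5' end of the 20-nt protospacer; the default
#' window of 4--8 reflects the high-activity window of BE3/BE4-class editors.
#'
#' @slot name Editor name, e.g. \code{"BE4"}.
#' @slot pam IUPAC PAM string, e.g. \code{"NGG"}.
#' @slot windowStart,windowEnd Integer protospacer positions bounding the
#'   editing window (inclusive), \code{1 <= windowStart <= windowEnd <= 20}.
#'
#' @seealso [baseEditorProfile()]
#' @export
setClass("BaseEditorProfile",
  representation(
    name = "character",
    pam = "character",
    windowStart = "integer",
    windowEnd = "integer"
  )
)

setValidity("BaseEditorProfile", function(object) {
  msg <- character()
  if (length(object@pam) != 1L || !nzchar(object@pam) ||
      !grepl("^[ACGTRYSWKMBDHVN]+$", object@pam))
    msg <- c(msg, "'pam' must be a non-empty IUPAC nucleotide string")
  ws <- object@windowStart
  we <- object@windowEnd
  if (length(ws) != 1L || length(we) != 1L || is.na(ws) || is.na(we) ||
      ws < 1L || ws > we || we > 20L)
    msg <- c(msg, "editing window must satisfy 1 <= windowStart <= windowEnd <= 20")
  if (length(msg)) msg else TRUE
})

#' Construct a base editor profile
#'
#' @param name Editor name.
#' @param pam IUPAC PAM string (default \code{"NGG"}, SpCas9).
#' @param windowStart,windowEnd Editing-window bounds in protospacer
#'   coordinates (1 = PAM-distal 5' base); defaults 4 and 8.
#' @return A [BaseEditorProfile-class] object.
#' @examples
#' be4 <- baseEditorProfile()
#' editingWindow(be4)
#' @export
baseEditorProfile <- function(name = "BE4", pam = "NGG",
                              windowStart = 4L, windowEnd = 8L) {
  new("BaseEditorProfile", name = as.character(name),
      pam = toupper(as.character(pam)),
      windowStart = as.integer(windowStart), windowEnd = as.integer(windowEnd))
}

#' Transcript model
#'
#' One transcript's exon/intron structure on a genome: exons as a
#' \code{GRanges} in transcript (5' to 3') order, an optional set of CDS
#' intervals, and identifiers. All exons must share one contig and strand;
#' minus-strand models expose their spliced sequence via reverse complement.
#'
#' @slot transcriptId,geneId Identifiers.
#' @slot exons \code{GRanges} of exons, transcript order.
#' @slot cds \code{GRanges} of coding intervals (possibly empty), transcript
#'   order; every interval must be contained in an exon.
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId = "character",
    exons = "GRanges",
    cds = "GRanges"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (length(ex) < 1L) {
    msg <- c(msg, "transcript must have at least one exon")
    return(msg)
  }
  if (length(unique(as.character(GenomeInfoDb::seqnames(ex)))) != 1L)
    msg <- c(msg, "all exons must lie on one contig")
  st <- unique(as.character(strand(ex)))
  if (length(st) != 1L || !st %in% c("+", "-"))
    msg <- c(msg, "exon strand must be uniformly '+' or '-'")
  if (length(ex) > 1L) {
    s <- start(ex); e <- end(ex)
    ok <- if (st == "+") all(diff(s) > 0) && all(e[-length(e)] < s[-1L])
          else all(diff(s) < 0) && all(s[-length(s)] > e[-1L])
    if (!isTRUE(ok))
      msg <- c(msg, "exons must be non-overlapping and in transcript (5'->3') order")
  }
  if (length(object@cds)) {
    hits <- GenomicRanges::findOverlaps(object@cds, ex, type = "within")
    if (length(unique(S4Vectors::queryHits(hits))) != length(object@cds))
      msg <- c(msg, "every CDS interval must be contained in an exon")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a transcript model
#'
#' @param transcriptId,geneId Identifiers.
#' @param exons \code{GRanges} of exons. They are re-ordered into transcript
#'   orientation (ascending genomic coordinate on '+', descending on '-').
#' @param cds Optional \code{GRanges} of coding intervals.
#' @return A [TranscriptModel-class].
#' @export
transcriptModel <- function(transcriptId, geneId = transcriptId, exons,
                            cds = GRanges()) {
  st <- unique(as.character(strand(exons)))
  if (length(st) == 1L && st %in% c("+", "-")) {
    ord <- order(start(exons), decreasing = (st == "-"))
    exons <- exons[ord]
    if (length(cds)) cds <- cds[order(start(cds), decreasing = (st == "-"))]
  }
  new("TranscriptModel", transcriptId = as.character(transcriptId),
      geneId = as.character(geneId), exons = exons, cds = cds)
}

#' Set of base-editor guide candidates
#'
#' A \code{GRanges}-derived container: one range per candidate giving the
#' genomic footprint of the 20-nt protospacer (the range strand is the
#' genomic strand the protospacer reads on), with candidate annotations in
#' the metadata columns: \code{protospacer}, \code{pam}, \code{strand_rel}
#' (sense/antisense relative to the pre-mRNA), \code{class}
#' (\code{splice_donor}/\code{splice_acceptor}/\code{pmstop}), target
#' addressing, critical and window cytosine positions, and scores.
#'
#' @export
setClass("GuideSet", contains = "GRanges")

.guide_mcols <- c("id", "transcript_id", "class", "protospacer", "pam",
                  "strand_rel", "target", "critical_pos", "window_cs",
                  "spliced_offset")

setValidity("GuideSet", function(object) {
  miss <- setdiff(.guide_mcols, colnames(mcols(object)))
  if (length(miss))
    return(paste("missing guide annotation column(s):",
                 paste(miss, collapse = ", ")))
  if (length(object) && any(nchar(mcols(object)$protospacer) != 20L))
    return("protospacers must be 20 nt")
  TRUE
})
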