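#' @importFrom GenomeInfoDb seqnames
NULL

#' @rdname TranscriptModel-class
#' @param object,x A \code{TranscriptModel}.
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("splicedLength", function(x) standardGeneric("splicedLength"))

#' Spliced (mature mRNA) sequence of a transcript
#'
#' @param x A \code{TranscriptModel}.
#' @param genome A \code{DNAStringSet} genome (see [readGenome()]).
#' @return A \code{DNAString} in transcript orientation.
#' @export
setGeneric("splicedSequence",
           function(x, genome) standardGeneric("splicedSequence"))

#' @rdname BaseEditorProfile-class
#' @param x A \code{BaseEditorProfile}.
#' @export
setGeneric("pamPattern", function(x) standardGeneric("pamPattern"))

#' @rdname BaseEditorProfile-class
#' @export
setGeneric("editingWindow", function(x) standardGeneric("editingWindow"))

#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)

#' @export
setMethod("geneId", "TranscriptModel", function(x) x@geneId)

#' @export
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)

#' @export
setMethod("cdsRanges", "TranscriptModel", function(x) x@cds)

#' @export
setMethod("splicedLength", "TranscriptModel",
          function(x) sum(width(x@exons)))

#' @export
setMethod("strand", "TranscriptModel",
          function(x) as.character(strand(x@exons))[1L])

#' @export
setMethod("seqnames", "TranscriptModel",
          function(x) as.character(seqnames(x@exons))[1L])

#' @export
setMethod("pamPattern", "BaseEditorProfile", function(x) x@pam)

#' @export
setMethod("editingWindow", "BaseEditorProfile",
          function(x) c(start = x@windowStart, end = x@windowEnd))

setMethod("show", "BaseEditorProfile", function(object) {
  cat("BaseEditorProfile '", object@name, "': PAM ", object@pam,
      ", editing window ", object@windowStart, "-", object@windowEnd,
      " (1 = PAM-distal)\n", sep = "")
})

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@transcriptId, " (gene ", object@geneId,
      ")\n  ", length(object@exons), " exon(s) on ", seqnames(object),
      " strand ", strand(object), "; spliced length ",
      splicedLength(object), " nt; ",
      if (length(object@cds)) paste0("CDS ", sum(width(object@cds)), " nt")
      else "no CDS", "\n", sep = "")
})

setMethod("show", "GuideSet", function(object) {
  cat("GuideSet with ", length(object), " candidate(s)\n", sep = "")
  if (length(object)) {
    tab <- table(mcols(object)$class)
    cat("  classes:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
    callNextMethod()
  }
})
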