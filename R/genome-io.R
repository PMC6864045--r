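#' Read a genome from a FASTA file
#'
#' Loads a (multi-)FASTA file into a \code{DNAStringSet}, uppercasing the
#' sequence. Soft-masked (lowercase) stretches are preserved as an
#' \code{IRanges} per contig in \code{metadata(x)$softmask}. Contig ids must
#' be unique; the file must be non-empty; characters outside the IUPAC
#' nucleotide alphabet are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A \code{DNAStringSet} keyed by contig id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGT"), fa)
#' g <- readGenome(fa)
#' width(g)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ## FASTA headers may carry descriptions after the id
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chars <- as.character(seqs)
  bad <- grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", chars)
  if (any(bad))
    stop("non-IUPAC characters in contig(s): ",
         paste(ids[bad], collapse = ", "))
  mask <- lapply(chars, function(s) {
    m <- gregexpr("[a-z]+", s)[[1L]]
    if (m[1L] == -1L) IRanges()
    else IRanges(start = as.integer(m), width = attr(m, "match.length"))
  })
  names(mask) <- ids
  out <- Biostrings::DNAStringSet(toupper(chars))
  names(out) <- ids
  metadata(out)$softmask <- mask
  out
}

#' Write a genome to FASTA
#'
#' Plain single-line-per-record writer (deterministic byte layout; a given
#' \code{DNAStringSet} always serializes identically).
#'
#' @param genome A \code{DNAStringSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenome <- function(genome, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(genome)) {
    writeLines(c(paste0(">", names(genome)[i]),
                 as.character(genome[[i]])), con, sep = "\n")
  }
  invisible(path)
}

#' Extract a genomic subsequence (0-based half-open)
#'
#' Convenience accessor using the 0-based half-open convention of the
#' package's exported tables; out-of-bounds lookups are an error.
#'
#' @param genome A \code{DNAStringSet}.
#' @param contig Contig id.
#' @param start0,end0 0-based half-open bounds.
#' @param strand \code{"+"} (default) or \code{"-"} (reverse complement).
#' @return Character scalar.
#' @export
getGenomeSequence <- function(genome, contig, start0, end0, strand = "+") {
  s <- .genome_sub0(genome, contig, start0, end0)
  if (identical(strand, "-")) reverseComplement0(s) else s
}
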