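## Tabular output. All genomic coordinates in exported tables are 0-based
## half-open (BED-style start0/end0 columns); GTF/GFF3 emitted by the
## fixture generator follow their own 1-based standards.

.write_tsv <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(d), collapse = "\t"), con, sep = "\n")
  if (nrow(d)) {
    rows <- do.call(paste, c(lapply(d, function(x) {
      if (is.numeric(x) && !is.integer(x)) format(x, digits = 15L,
                                                  scientific = FALSE,
                                                  trim = TRUE)
      else as.character(x)
    }), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Write a guide candidate table as TSV
#'
#' One row per candidate: transcript, class, protospacer, PAM, strand
#' (relative to the pre-mRNA), contig, 0-based half-open footprint, genomic
#' strand, critical and window-C protospacer positions, and the three
#' scores (when present).
#'
#' @param guides A [GuideSet-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGuideTable <- function(guides, path) {
  m <- mcols(guides)
  d <- data.frame(
    transcript = m$transcript_id, class = m$class, target = m$target,
    protospacer = m$protospacer, pam = m$pam, strand_rel = m$strand_rel,
    contig = as.character(seqnames(guides)),
    start0 = start(guides) - 1L, end0 = end(guides),
    genomic_strand = as.character(strand(guides)),
    critical_pos = m$critical_pos, window_cs = m$window_cs,
    stringsAsFactors = FALSE)
  for (col in c("window_score", "transcript_score", "combined_score"))
    if (!is.null(m[[col]])) d[[col]] <- round(m[[col]], 6L)
  .write_tsv(d, path)
}

#' Write guide genomic footprints as BED6
#'
#' 0-based half-open intervals; name = \code{class:transcript:target},
#' score = \code{round(1000 * combined_score)}, strand = genomic strand of
#' the protospacer.
#'
#' @inheritParams writeGuideTable
#' @export
writeGuideBed <- function(guides, path) {
  m <- mcols(guides)
  score <- if (is.null(m$combined_score)) rep(0L, length(guides))
           else as.integer(round(1000 * m$combined_score))
  d <- data.frame(
    chrom = as.character(seqnames(guides)),
    start = start(guides) - 1L, end = end(guides),
    name = paste(m$class, m$transcript_id, m$target, sep = ":"),
    score = score, strand = as.character(strand(guides)),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(d))
    writeLines(do.call(paste, c(d, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a ddPCR droplet-count table and append frequencies
#'
#' Expects columns \code{assay}, \code{n}, \code{k_fam}, \code{k_hex}
#' (TSV or CSV by extension); appends a \code{frequency_pct} column
#' computed with [ddpcrTranslocationFrequency()].
#'
#' @param path Input table.
#' @param variant Passed to [ddpcrTranslocationFrequency()].
#' @return \code{data.frame} with the computed column.
#' @export
readDdpcrTable <- function(path, variant = "two_copy_ratio") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("assay", "n", "k_fam", "k_hex")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d$frequency_pct <- vapply(seq_len(nrow(d)), function(i)
    ddpcrTranslocationFrequency(d$n[i], d$k_fam[i], d$k_hex[i],
                                variant = variant), numeric(1L))
  d
}
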