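## Small sequence helpers shared across modules. Character-level on purpose:
## guide scanning works on short extracted windows where string ops are
## clearer (and faster) than round-tripping through XString objects.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverseComplement0 <- function(x) {
  vapply(x, function(s) {
    paste(rev(.COMPLEMENT[strsplit(toupper(s), "", fixed = TRUE)[[1L]]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

.complement_base <- function(b) unname(.COMPLEMENT[b])

## does concrete sequence `seq` (A/C/G/T/N) match IUPAC `pattern`, same length?
## N in the sequence never matches (unknown base disqualifies).
.iupac_match <- function(seq, pattern) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (length(s) != length(p)) return(FALSE)
  all(vapply(seq_along(s),
             function(i) s[i] %in% .IUPAC[[p[i]]],
             logical(1L)))
}

## deterministic local RNG scope: fixed generator kind so the same seed gives
## the same stream across R installations
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

## 0-based half-open genome substring lookup with bounds checks
.genome_sub0 <- function(genome, contig, start0, end0) {
  if (!contig %in% names(genome))
    stop("unknown contig '", contig, "'")
  w <- length(genome[[contig]])
  if (start0 < 0L || end0 > w || start0 >= end0)
    stop("coordinates [", start0, ", ", end0, ") outside contig '",
         contig, "' (length ", w, ") or empty")
  as.character(Biostrings::subseq(genome[[contig]], start0 + 1L, end0))
}

.stop_codons <- c("TAA", "TAG", "TGA")

.translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}
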