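#' Score guide candidates
#'
#' Two component scores, both in \code{[0, 1]}:
#' \describe{
#'   \item{window score}{\code{max(0, 1 - |p - p_mid| / half_span)} where
#'     \code{p} is the critical protospacer position (mean when a candidate
#'     has several), \code{p_mid} the window midpoint (6 for window 4--8),
#'     and \code{half_span = windowEnd - windowStart} (4 for window 4--8).
#'     Guides whose critical C sits at the center of the deamination window
#'     score 1.}
#'   \item{transcript score}{\code{1 - d / L} with \code{d} the 0-based
#'     spliced-transcript offset of the targeted junction or codon and
#'     \code{L} the spliced transcript length: earlier targets score
#'     higher, since upstream disruption truncates more of the product.}
#' }
#' The combined score is a convex combination (default weights 0.7 window /
#' 0.3 transcript), clamped to \code{[0, 1]}.
#'
#' @param guides A [GuideSet-class] from the finders.
#' @param tm The [TranscriptModel-class] the guides were designed against.
#' @param profile The [BaseEditorProfile-class] used.
#' @param weights Numeric \code{c(window =, transcript =)} mixing weights;
#'   normalized to sum to 1.
#' @return The [GuideSet-class] with \code{window_score},
#'   \code{transcript_score} and \code{combined_score} columns.
#' @export
scoreGuides <- function(guides, tm, profile = baseEditorProfile(),
                        weights = c(window = 0.7, transcript = 0.3)) {
  stopifnot(is(guides, "GuideSet"))
  weights <- weights / sum(weights)
  win <- editingWindow(profile)
  p_mid <- (win[["start"]] + win[["end"]]) / 2
  half_span <- max(win[["end"]] - win[["start"]], 1L)
  L <- splicedLength(tm)
  n <- length(guides)
  wsc <- tsc <- numeric(n)
  for (i in seq_len(n)) {
    p <- mean(.pos_split(mcols(guides)$critical_pos[i]))
    wsc[i] <- max(0, 1 - abs(p - p_mid) / half_span)
    d <- mcols(guides)$spliced_offset[i]
    tsc[i] <- min(1, max(0, 1 - d / L))
  }
  mcols(guides)$window_score <- wsc
  mcols(guides)$transcript_score <- tsc
  mcols(guides)$combined_score <- pmin(1, pmax(0,
    weights[["window"]] * wsc + weights[["transcript"]] * tsc))
  guides
}

#' Rank scored guide candidates
#'
#' Orders by descending combined score; ties broken by higher window score,
#' then smaller spliced-transcript offset, then lexicographic protospacer.
#' The ordering is deterministic for any input permutation.
#'
#' @param guides A scored [GuideSet-class].
#' @return The [GuideSet-class], reordered.
#' @export
rankGuides <- function(guides) {
  stopifnot(is(guides, "GuideSet"))
  if (!length(guides)) return(guides)
  if (is.null(mcols(guides)$combined_score))
    stop("guides must be scored first (see scoreGuides)")
  m <- mcols(guides)
  ord <- order(-m$combined_score, -m$window_score, m$spliced_offset,
               m$protospacer, m$id)
  guides[ord]
}
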