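#' Translocation frequency from duplexed ddPCR droplet counts
#'
#' Droplet digital PCR partitions the sample into \code{n} droplets; the
#' per-droplet target copy number is Poisson, so the concentration of a
#' species with \code{k} positive droplets is \code{lambda = -ln(1 - k/n)}
#' copies per droplet. A duplexed assay pairs an experimental junction probe
#' (FAM) with an internal reference probe (HEX) present at two copies per
#' diploid genome; the junction frequency per genome is therefore
#' \deqn{f = 100 \cdot 2 \cdot \lambda_{FAM} / \lambda_{HEX}} (percent).
#' The alternative \code{"fractional_abundance"} variant doubles the
#' QuantaSoft-style fractional abundance
#' \code{lambda_FAM / (lambda_FAM + lambda_HEX)} instead.
#'
#' @param n Total droplets (> 0).
#' @param kFam FAM-positive droplets (junction probe), \code{0 <= kFam <= n};
#'   a saturated channel (\code{kFam == n}) is an error.
#' @param kHex HEX-positive droplets (reference probe); must satisfy
#'   \code{0 < kHex < n} (no signal or saturation is an error).
#' @param variant \code{"two_copy_ratio"} (default) or
#'   \code{"fractional_abundance"}.
#' @return Frequency as a percentage (0 when \code{kFam == 0}).
#' @examples
#' ddpcrTranslocationFrequency(n = 10000, kFam = 10, kHex = 5000) # ~0.289%
#' @export
ddpcrTranslocationFrequency <- function(n, kFam, kHex,
                                        variant = c("two_copy_ratio",
                                                    "fractional_abundance")) {
  variant <- match.arg(variant)
  n <- as.numeric(n); kFam <- as.numeric(kFam); kHex <- as.numeric(kHex)
  if (is.na(n) || n <= 0) stop("droplet count n must be positive")
  if (kFam < 0 || kFam > n || kHex < 0 || kHex > n)
    stop("positive-droplet counts must lie in [0, n]")
  if (kHex == 0) stop("no reference (HEX) signal: cannot normalize")
  if (kHex == n) stop("reference (HEX) channel saturated: all droplets positive")
  if (kFam == n) stop("target (FAM) channel saturated: all droplets positive")
  if (kFam == 0) return(0)
  lam_fam <- -log1p(-kFam / n)
  lam_hex <- -log1p(-kHex / n)
  switch(variant,
         two_copy_ratio = 100 * 2 * lam_fam / lam_hex,
         fractional_abundance = 100 * 2 * lam_fam / (lam_fam + lam_hex))
}

#' Normalize PD-1 flow cytometry fractions
#'
#' Stimulation does not upregulate PD-1 uniformly in control T cells, so
#' observed PD-1 positive/negative fractions are rescaled using the
#' control-sample ratio \code{rPd1} of PD-1+ to PD-1- subpopulations:
#' \deqn{F'_{pos} = F^\circ_{pos} + F^\circ_{pos} (1 - r_{PD1})}
#' \deqn{F'_{neg} = F^\circ_{neg} - F^\circ_{pos} (1 - r_{PD1})}
#' The correction moves mass between the two gates, so
#' \code{pos + neg} is conserved exactly.
#'
#' @param fPos,fNeg Non-normalized positive/negative percentages.
#' @param rPd1 Control-sample PD-1+/PD-1- ratio (> 0).
#' @param clamp Clamp results into \code{[0, 100]} (default \code{FALSE});
#'   out-of-range results are flagged either way.
#' @return A \code{data.frame} with \code{f_pos}, \code{f_neg},
#'   \code{out_of_range}.
#' @examples
#' normalizePd1(40, 60, 0.8) # 48 / 52
#' @export
normalizePd1 <- function(fPos, fNeg, rPd1, clamp = FALSE) {
  if (any(rPd1 <= 0)) stop("rPd1 must be positive")
  if (any(fPos < 0) || any(fNeg < 0))
    stop("fractions must be non-negative percentages")
  if (any(fPos + fNeg > 100 + 1e-6))
    stop("fPos + fNeg exceeds 100%")
  shift <- fPos * (1 - rPd1)
  pos <- fPos + shift
  ## algebraically fNeg - shift; written so pos + neg conserves the input
  ## total to the last bit
  neg <- (fPos + fNeg) - pos
  oor <- pos < 0 | pos > 100 | neg < 0 | neg > 100
  if (any(oor))
    warning("normalized fraction(s) outside [0, 100]",
            if (clamp) "; clamped" else "")
  if (clamp) {
    pos <- pmin(100, pmax(0, pos))
    neg <- pmin(100, pmax(0, neg))
  }
  data.frame(f_pos = pos, f_neg = neg, out_of_range = oor)
}

#' Rank RNA off-target candidate genes by expression
#'
#' Deaminase overexpression can edit abundant RNA transcripts independently
#' of the sgRNA; candidate genes for targeted follow-up are those both
#' highly expressed in the assayed cell types and previously observed to be
#' edited. Each gene's score is its percent-maximal expression,
#' \deqn{score_i = (Reads^i_{CD4} \cdot Reads^i_{CD8}) /
#'   \max_j (Reads^j_{CD4} \cdot Reads^j_{CD8})}
#' (the denominator maximizes the per-gene product over all input genes).
#'
#' @param records \code{data.frame} with columns \code{gene},
#'   \code{reads_cd4}, \code{reads_cd8}, \code{previously_edited}.
#' @param topN Number of candidates to return (default 5).
#' @return \code{records} restricted to previously edited genes, with a
#'   \code{score} column, sorted by descending score (ties by gene id),
#'   truncated to \code{topN} rows.
#' @export
rankRnaOtCandidates <- function(records, topN = 5L) {
  need <- c("gene", "reads_cd4", "reads_cd8", "previously_edited")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("no expression records")
  if (any(records$reads_cd4 < 0) || any(records$reads_cd8 < 0))
    stop("read counts must be non-negative")
  prod <- as.numeric(records$reads_cd4) * as.numeric(records$reads_cd8)
  if (max(prod) == 0) stop("all expression products are zero")
  records$score <- prod / max(prod)
  out <- records[records$previously_edited, , drop = FALSE]
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  utils::head(out, n = max(1L, as.integer(topN)))
}
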