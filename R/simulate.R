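#' Simulate per-cell knockout calls
#'
#' Independent Bernoulli knockout per gene per cell at the given rates;
#' reproducible by seed (fixed Mersenne-Twister stream).
#'
#' @param rates Named per-gene knockout probabilities in \code{[0, 1]}.
#' @param nCells Number of cells (>= 1).
#' @param seed Integer seed.
#' @return Logical matrix, \code{nCells} rows x \code{length(rates)} named
#'   columns.
#' @examples
#' m <- simulateKoCalls(c(TRAC = 0.9, B2M = 0.9, PDCD1 = 0.9), 1000, seed = 1)
#' colMeans(m)
#' @export
simulateKoCalls <- function(rates, nCells, seed) {
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    stop("knockout rates must lie in [0, 1]")
  nCells <- as.integer(nCells)
  if (nCells < 1L) stop("nCells must be >= 1")
  genes <- names(rates)
  if (is.null(genes)) genes <- paste0("gene", seq_along(rates))
  .with_seed(seed, {
    m <- vapply(rates, function(p)
      stats::runif(nCells) < p, logical(nCells))
    m <- matrix(m, nrow = nCells, dimnames = list(NULL, genes))
    m
  })
}

#' Simulate duplexed ddPCR droplet counts
#'
#' Generative model matching the estimator in
#' [ddpcrTranslocationFrequency()]: the reference (HEX) species has Poisson
#' concentration \code{referenceLambda} copies per droplet, the junction
#' (FAM) species \code{lambda_fam = trueFrequency/100 * referenceLambda / 2}
#' (frequency is junctions per diploid genome, the reference being present
#' at two copies). Positive-droplet counts are binomial with per-droplet
#' occupancy \code{1 - exp(-lambda)}.
#'
#' @param trueFrequency True junction frequency, percent.
#' @param nDroplets Droplets generated (>= 1).
#' @param referenceLambda Reference concentration, copies/droplet (> 0).
#' @param seed Integer seed.
#' @return List with \code{n}, \code{k_fam}, \code{k_hex}.
#' @export
simulateDdpcr <- function(trueFrequency, nDroplets, referenceLambda = 0.7,
                          seed = 1L) {
  if (trueFrequency < 0) stop("trueFrequency must be >= 0")
  nDroplets <- as.integer(nDroplets)
  if (nDroplets < 1L) stop("nDroplets must be >= 1")
  if (referenceLambda <= 0) stop("referenceLambda must be > 0")
  lam_fam <- trueFrequency / 100 * referenceLambda / 2
  .with_seed(seed, {
    k_hex <- stats::rbinom(1L, nDroplets, 1 - exp(-referenceLambda))
    k_fam <- stats::rbinom(1L, nDroplets, 1 - exp(-lam_fam))
    list(n = nDroplets, k_fam = k_fam, k_hex = k_hex)
  })
}
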