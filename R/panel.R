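#' Define a multiplex panel of DSB/edit loci
#'
#' @param label Unique locus labels.
#' @param contig,coord Optional genomic location (0-based cut coordinate).
#' @param kind \code{"on_target"} or \code{"off_target"} per locus.
#' @return A \code{data.frame} with columns \code{label}, \code{contig},
#'   \code{coord}, \code{kind}.
#' @export
panelLoci <- function(label, contig = NA_character_, coord = NA_integer_,
                      kind = "on_target") {
  if (anyDuplicated(label))
    stop("duplicate panel labels: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  data.frame(label = as.character(label),
             contig = rep_len(as.character(contig), length(label)),
             coord = rep_len(as.integer(coord), length(label)),
             kind = rep_len(as.character(kind), length(label)),
             stringsAsFactors = FALSE)
}

#' Enumerate directed translocation junction outcomes
#'
#' Simultaneous double-strand breaks at \code{k} loci admit
#' \code{k * (k - 1)} directed fusion junctions: each unordered pair of loci
#' contributes both reciprocal junctions, which are distinct molecular
#' outcomes (and distinct ddPCR assays). Four loci -- e.g. three on-target
#' sites plus one off-target site -- give 12 outcomes; ten loci give 90.
#' Inversions and large deletions are not counted.
#'
#' @param panel A \code{data.frame} from [panelLoci()] (or any data frame
#'   with a \code{label} column), or a character vector of labels.
#' @return A \code{data.frame} with columns \code{partner_a},
#'   \code{partner_b}, \code{orientation} (\code{"a_to_b"}), one row per
#'   directed junction; \code{k < 2} gives zero rows.
#' @examples
#' nrow(enumerateTranslocations(c("TRAC", "B2M", "PDCD1", "PDCD1_OT"))) # 12
#' @export
enumerateTranslocations <- function(panel) {
  labels <- if (is.character(panel)) panel else panel$label
  if (anyDuplicated(labels))
    stop("duplicate panel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  k <- length(labels)
  if (k < 2L)
    return(data.frame(partner_a = character(), partner_b = character(),
                      orientation = character(), stringsAsFactors = FALSE))
  grid <- expand.grid(b = seq_len(k), a = seq_len(k))
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  grid <- grid[order(grid$a, grid$b), , drop = FALSE]
  data.frame(partner_a = labels[grid$a], partner_b = labels[grid$b],
             orientation = "a_to_b", stringsAsFactors = FALSE)
}

#' Knockout-combination fractions from per-cell calls
#'
#' Decomposes a boolean knockout-call matrix (rows = cells, columns = genes)
#' into the fraction of cells in each of the \code{2^g} combination
#' categories, plus the grouped fractions by number of genes lost
#' (0 .. \code{g}). Both groupings sum to 1.
#'
#' @param m Logical matrix (or coercible), named columns.
#' @return List with \code{combinations} (\code{data.frame}: per-gene
#'   pattern, category label, count, fraction) and \code{by_count}
#'   (\code{data.frame}: \code{n_ko}, count, fraction).
#' @export
koCombinationFractions <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L || nrow(m) == 0L) stop("empty knockout-call matrix")
  storage.mode(m) <- "logical"
  if (anyNA(m)) stop("knockout calls must be TRUE/FALSE, no NA")
  g <- ncol(m)
  genes <- colnames(m)
  if (is.null(genes)) genes <- paste0("gene", seq_len(g))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), g))[, rev(seq_len(g)),
                                                      drop = FALSE]
  colnames(combos) <- genes
  key <- apply(m, 1L, function(x) paste(as.integer(x), collapse = ""))
  ckey <- apply(combos, 1L, function(x) paste(as.integer(x), collapse = ""))
  counts <- as.integer(table(factor(key, levels = ckey)))
  label <- apply(combos, 1L, function(x) {
    lost <- genes[as.logical(x)]
    if (length(lost)) paste(lost, collapse = "+") else "WT"
  })
  comb <- data.frame(combos, category = label, count = counts,
                     fraction = counts / nrow(m), stringsAsFactors = FALSE,
                     check.names = FALSE)
  nko <- rowSums(m)
  bc <- as.integer(table(factor(nko, levels = 0:g)))
  list(combinations = comb,
       by_count = data.frame(n_ko = 0:g, count = bc,
                             fraction = bc / nrow(m)))
}

#' Expected combination fractions under independent editing
#'
#' Benchmark composition for comparing an observed multiplex knockout
#' population against the independence assumption: the probability of each
#' of the \code{2^g} categories is the product of per-gene knockout (or
#' retention) probabilities.
#'
#' @param rates Named numeric vector of per-gene knockout probabilities in
#'   \code{[0, 1]}.
#' @return List as in [koCombinationFractions()] with \code{fraction}
#'   columns holding probabilities (no counts).
#' @examples
#' expectedCombinationFractions(c(TRAC = 0.9, B2M = 0.9, PDCD1 = 0.9))
#' @export
expectedCombinationFractions <- function(rates) {
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    stop("knockout rates must lie in [0, 1]")
  g <- length(rates)
  genes <- names(rates)
  if (is.null(genes)) genes <- paste0("gene", seq_len(g))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), g))[, rev(seq_len(g)),
                                                      drop = FALSE]
  colnames(combos) <- genes
  prob <- apply(combos, 1L, function(x)
    prod(ifelse(as.logical(x), rates, 1 - rates)))
  label <- apply(combos, 1L, function(x) {
    lost <- genes[as.logical(x)]
    if (length(lost)) paste(lost, collapse = "+") else "WT"
  })
  nko <- rowSums(combos)
  by_count <- vapply(0:g, function(i) sum(prob[nko == i]), numeric(1L))
  list(combinations = data.frame(combos, category = label, fraction = prob,
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE),
       by_count = data.frame(n_ko = 0:g, fraction = by_count))
}
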