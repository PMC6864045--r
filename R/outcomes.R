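## Outcome enumeration and consequence classification. Cytosine base editors
## convert window Cs predominantly to T, but nontarget C->A and C->G edits
## occur; every joint assignment over the window Cs is therefore enumerated
## (4^m outcomes including all-unchanged) and classified at the sense level.

.EDIT_BASES <- c("unchanged", "T", "A", "G")

.parse_assignment <- function(a) {
  if (!nzchar(a)) return(data.frame(pos = integer(), base = character()))
  parts <- strsplit(a, ";", fixed = TRUE)[[1L]]
  data.frame(pos = as.integer(sub("[TAG]$", "", parts)),
             base = sub("^[0-9]+", "", parts), stringsAsFactors = FALSE)
}

#' Enumerate all joint edit outcomes of a guide candidate
#'
#' For a candidate with \code{m} window cytosines, every assignment of
#' \{unchanged, T, A, G\} to each window C is generated (\code{4^m}
#' outcomes, including the all-unchanged one). The assignment is encoded as
#' a string such as \code{"6T"} or \code{"4A;6T"} (protospacer position +
#' new base on the protospacer strand; empty string = unchanged).
#'
#' @param guide A length-1 [GuideSet-class].
#' @param profile The [BaseEditorProfile-class] (window definition).
#' @return A \code{data.frame} with columns \code{guide_id},
#'   \code{assignment}, \code{edited_protospacer}, and \code{sense_local}
#'   (sense-strand rendering of the edited protospacer footprint).
#' @export
enumerateOutcomes <- function(guide, profile = baseEditorProfile()) {
  stopifnot(is(guide, "GuideSet"), length(guide) == 1L)
  P <- .pos_split(mcols(guide)$window_cs)
  m <- length(P)
  if (m > 8L)
    stop("candidate has ", m, " window cytosines (4^m = ", 4^m,
         " outcomes); use sampling rather than exhaustive enumeration")
  proto <- mcols(guide)$protospacer
  grids <- rep(list(.EDIT_BASES), m)
  grid <- if (m == 0L) data.frame(row.names = 1L)
          else expand.grid(grids, stringsAsFactors = FALSE)
  n <- nrow(grid)
  assignment <- character(n)
  edited <- character(n)
  for (r in seq_len(n)) {
    pr <- proto
    parts <- character()
    for (j in seq_len(m)) {
      b <- grid[r, j]
      if (b != "unchanged") {
        substr(pr, P[j], P[j]) <- b
        parts <- c(parts, paste0(P[j], b))
      }
    }
    assignment[r] <- paste(parts, collapse = ";")
    edited[r] <- pr
  }
  sense_local <- if (mcols(guide)$strand_rel == "sense") edited
                 else reverseComplement0(edited)
  data.frame(guide_id = mcols(guide)$id, assignment = assignment,
             edited_protospacer = edited, sense_local = sense_local,
             stringsAsFactors = FALSE)
}

## plus-strand genomic coordinate of protospacer position p
.proto_pos_to_plus <- function(guide, p) {
  if (as.character(strand(guide)) == "+") start(guide) + p - 1L
  else end(guide) - p + 1L
}

## plus-strand base resulting from editing protospacer position to `base`
.edit_plus_base <- function(guide, base) {
  if (as.character(strand(guide)) == "+") base else .complement_base(base)
}

#' Classify enumerated outcomes by functional consequence
#'
#' Splice-class candidates: the junction dinucleotide is reconstructed on
#' the sense strand after the edits; a donor that no longer reads \code{GT}
#' is \code{splice_donor_lost} (predicted effect: intron retention followed
#' by nonsense-mediated decay), an acceptor that no longer reads \code{AG}
#' is \code{splice_acceptor_lost} (predicted effect: exon skipping).
#' pmSTOP-class candidates: every CDS codon touched by an edit is
#' translated; a new stop codon gives \code{pmstop} (truncation), an amino
#' acid change \code{missense}, a synonymous change \code{silent}.
#' Acceptor guides feeding the final or a noncoding exon are flagged
#' \code{noncoding_or_terminal_exon} (protein knockout is not assured);
#' skipped exons whose length is a multiple of 3 add \code{in_frame_skip}.
#' Outcomes whose edits are exclusively nontarget conversions (C to A/G)
#' are flagged \code{nontarget_only}.
#'
#' @param outcomes Output of [enumerateOutcomes()].
#' @param guide The length-1 [GuideSet-class] the outcomes belong to.
#' @param tm The [TranscriptModel-class].
#' @param genome A \code{DNAStringSet}.
#' @return \code{outcomes} with \code{consequence}, \code{effect} and
#'   \code{flags} columns appended.
#' @export
classifyOutcomes <- function(outcomes, guide, tm, genome) {
  stopifnot(is(guide, "GuideSet"), length(guide) == 1L)
  cls <- mcols(guide)$class
  tx_minus <- mcols(guide)$tx_strand == "-"
  contig <- as.character(seqnames(guide))
  map <- if (cls == "pmstop") .cds_map(tm) else NULL
  codons <- if (cls == "pmstop") .codon_table(tm, genome, map) else NULL

  n <- nrow(outcomes)
  consequence <- rep("none", n)
  effect <- rep("none", n)
  flags <- character(n)

  base_flags <- character()
  if (cls == "splice_acceptor") {
    if (isTRUE(mcols(guide)$last_exon) ||
        !isTRUE(mcols(guide)$downstream_exon_coding))
      base_flags <- c(base_flags, "noncoding_or_terminal_exon")
    if (mcols(guide)$downstream_exon_len %% 3L == 0L)
      base_flags <- c(base_flags, "in_frame_skip")
  }

  junc_lo <- mcols(guide)$junction_lo
  junc_plus <- if (cls != "pmstop")
    .genome_sub0(genome, contig, junc_lo - 1L, junc_lo + 1L) else NULL

  for (r in seq_len(n)) {
    ed <- .parse_assignment(outcomes$assignment[r])
    fl <- base_flags
    if (nrow(ed)) {
      if (all(ed$base %in% c("A", "G")))
        fl <- c(fl, "nontarget_only")
      plus_pos <- vapply(ed$pos, function(p) .proto_pos_to_plus(guide, p),
                         integer(1L))
      plus_base <- vapply(ed$base, function(b) .edit_plus_base(guide, b),
                          character(1L))
      if (cls %in% c("splice_donor", "splice_acceptor")) {
        dinuc <- strsplit(junc_plus, "", fixed = TRUE)[[1L]]
        hit <- plus_pos %in% c(junc_lo, junc_lo + 1L)
        if (any(hit)) {
          idx <- plus_pos[hit] - junc_lo + 1L
          dinuc[idx] <- plus_base[hit]
        }
        sense_dinuc <- paste(dinuc, collapse = "")
        if (tx_minus) sense_dinuc <- reverseComplement0(sense_dinuc)
        if (cls == "splice_donor" && sense_dinuc != "GT") {
          consequence[r] <- "splice_donor_lost"
          effect[r] <- "intron_retention_nmd"
        } else if (cls == "splice_acceptor" && sense_dinuc != "AG") {
          consequence[r] <- "splice_acceptor_lost"
          effect[r] <- "exon_skipping"
        } else if (nrow(ed)) {
          consequence[r] <- "silent"
        }
      } else {  # pmstop
        in_cds <- match(plus_pos, map$genomic)
        touched <- unique(map$codon[in_cds[!is.na(in_cds)]])
        any_stop <- FALSE; any_missense <- FALSE; any_change <- FALSE
        for (k in touched) {
          ref <- codons$seq[codons$codon == k]
          cod <- strsplit(ref, "", fixed = TRUE)[[1L]]
          rows <- which(!is.na(in_cds) & map$codon[in_cds] == k)
          for (j in rows) {
            cp <- map$codon_pos[in_cds[j]]
            b <- plus_base[j]
            cod[cp] <- if (tx_minus) .complement_base(b) else b
          }
          new <- paste(cod, collapse = "")
          if (new != ref) any_change <- TRUE
          if (new %in% .stop_codons && !(ref %in% .stop_codons)) {
            any_stop <- TRUE
          } else if (!is.na(.translate_codon(new)) &&
                     !identical(.translate_codon(new),
                                .translate_codon(ref))) {
            any_missense <- TRUE
          }
        }
        if (any_stop) {
          consequence[r] <- "pmstop"; effect[r] <- "truncation"
        } else if (any_missense) {
          consequence[r] <- "missense"
        } else {
          consequence[r] <- "silent"
        }
      }
    }
    flags[r] <- paste(fl, collapse = ",")
  }
  outcomes$consequence <- consequence
  outcomes$effect <- effect
  outcomes$flags <- flags
  outcomes
}

#' Summarize a candidate over its classified outcomes
#'
#' Restricts to outcomes in which at least one knockout-critical position is
#' edited at all, then reports the fraction classified knockout-causing
#' (splice-site loss or premature stop), missense, and silent.
#'
#' @param guide A length-1 [GuideSet-class].
#' @param outcomes Classified outcomes from [classifyOutcomes()].
#' @return A one-row \code{data.frame} (zero rows, with a warning, when the
#'   candidate has no window cytosines).
#' @export
summarizeCandidate <- function(guide, outcomes) {
  stopifnot(is(guide, "GuideSet"), length(guide) == 1L)
  crit <- .pos_split(mcols(guide)$critical_pos)
  template <- data.frame(guide_id = character(), class = character(),
                         n_outcomes = integer(), n_critical_edited = integer(),
                         frac_knockout = numeric(), frac_missense = numeric(),
                         frac_silent = numeric(), flags = character(),
                         stringsAsFactors = FALSE)
  if (!nzchar(mcols(guide)$window_cs)) {
    warning("candidate ", mcols(guide)$id,
            " has no window cytosines; empty summary")
    return(template)
  }
  edited_crit <- vapply(outcomes$assignment, function(a) {
    ed <- .parse_assignment(a)
    any(ed$pos %in% crit)
  }, logical(1L), USE.NAMES = FALSE)
  sub <- outcomes[edited_crit, , drop = FALSE]
  ko <- c("splice_donor_lost", "splice_acceptor_lost", "pmstop")
  data.frame(guide_id = mcols(guide)$id, class = mcols(guide)$class,
             n_outcomes = nrow(outcomes), n_critical_edited = nrow(sub),
             frac_knockout = mean(sub$consequence %in% ko),
             frac_missense = mean(sub$consequence == "missense"),
             frac_silent = mean(sub$consequence == "silent"),
             flags = outcomes$flags[1L],
             stringsAsFactors = FALSE)
}
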