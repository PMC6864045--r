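#' End-to-end guide design run
#'
#' Loads a genome and annotation, designs splice-disrupting and pmSTOP
#' guides for the requested transcripts, scores and ranks them, enumerates
#' and classifies every edit outcome per candidate, and writes the guide
#' table, BED footprints, outcome table and per-candidate summary to
#' \code{outDir}. Outputs are deterministic for fixed inputs and
#' configuration.
#'
#' @param config A \code{RunConfig} from [runConfig()].
#' @param genomePath FASTA path.
#' @param annotationPath GTF/GFF3 path.
#' @param transcriptIds Character vector of transcript ids to design for;
#'   must be non-empty and present in the annotation.
#' @param outDir Output directory (created if needed).
#' @param classes Guide classes to design: subset of
#'   \code{c("splice", "pmstop")}.
#' @return Invisibly, a list with \code{guides} ([GuideSet-class]),
#'   \code{outcomes}, \code{summary} (data frames) and \code{files}.
#' @export
runDesign <- function(config, genomePath, annotationPath, transcriptIds,
                      outDir, classes = c("splice", "pmstop")) {
  if (!inherits(config, "RunConfig")) stop("config must be a RunConfig")
  if (length(transcriptIds) == 0L)
    stop("no transcript ids given")
  classes <- match.arg(classes, several.ok = TRUE)
  genome <- readGenome(genomePath)
  models <- readTranscripts(annotationPath, genome)
  unknown <- setdiff(transcriptIds, names(models))
  if (length(unknown))
    stop("unknown transcript id(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(models), collapse = ", "))
  profile <- .config_profile(config)
  weights <- c(window = config$weightWindow,
               transcript = config$weightTranscript)

  all_guides <- NULL
  outcome_rows <- list()
  summary_rows <- list()
  for (tid in transcriptIds) {
    tm <- models[[tid]]
    gs <- list()
    if ("splice" %in% classes && length(tm@exons) >= 2L)
      gs <- c(gs, list(findSpliceGuides(tm, genome, profile, config$flank,
                                        config$includeNoncanonical)))
    if ("pmstop" %in% classes && length(tm@cds))
      gs <- c(gs, list(findPmstopGuides(tm, genome, profile)))
    if (!length(gs)) next
    guides <- new("GuideSet",
                  do.call(c, lapply(gs, as, Class = "GRanges")))
    guides <- rankGuides(scoreGuides(guides, tm, profile, weights))
    message("spliceCBE: ", tid, ": ", length(guides), " candidate(s)")
    for (i in seq_along(guides)) {
      g <- guides[i]
      out <- classifyOutcomes(enumerateOutcomes(g, profile), g, tm, genome)
      outcome_rows[[length(outcome_rows) + 1L]] <- out
      if (nzchar(mcols(g)$window_cs))
        summary_rows[[length(summary_rows) + 1L]] <-
          summarizeCandidate(g, out)
    }
    all_guides <- if (is.null(all_guides)) guides
                  else new("GuideSet", c(as(all_guides, "GRanges"),
                                         as(guides, "GRanges")))
  }
  if (is.null(all_guides))
    all_guides <- .records_to_guideset(.empty_guide_records(), "none")
  outcomes <- if (length(outcome_rows)) do.call(rbind, outcome_rows)
              else data.frame()
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows)
             else data.frame()

  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  files <- c(
    guides = file.path(outDir, "guides.tsv"),
    bed = file.path(outDir, "guides.bed"),
    outcomes = file.path(outDir, "outcomes.tsv"),
    summary = file.path(outDir, "summary.tsv"))
  writeGuideTable(all_guides, files[["guides"]])
  writeGuideBed(all_guides, files[["bed"]])
  .write_tsv(outcomes, files[["outcomes"]])
  .write_tsv(summary, files[["summary"]])
  invisible(list(guides = all_guides, outcomes = outcomes,
                 summary = summary, files = files))
}
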