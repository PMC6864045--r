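#' Run configuration
#'
#' All tunable parameters of a design run in one serializable object
#' (YAML round-trip): editor profile, splice-window flank, scoring weights,
#' ddPCR formula variant, reporting threshold, and seed.
#'
#' @param editor Editor name.
#' @param pam IUPAC PAM.
#' @param windowStart,windowEnd Editing window bounds.
#' @param flank Splice-window flank (>= 20).
#' @param weightWindow,weightTranscript Scoring weights.
#' @param ddpcrVariant \code{"two_copy_ratio"} or
#'   \code{"fractional_abundance"}.
#' @param detectionLimitPct ddPCR reporting threshold, percent.
#' @param includeNoncanonical Design against non-GT/AG junctions.
#' @param seed Integer seed for anything stochastic.
#' @return A \code{list} of class \code{"RunConfig"}.
#' @export
runConfig <- function(editor = "BE4", pam = "NGG", windowStart = 4L,
                      windowEnd = 8L, flank = 30L, weightWindow = 0.7,
                      weightTranscript = 0.3,
                      ddpcrVariant = "two_copy_ratio",
                      detectionLimitPct = 0.01,
                      includeNoncanonical = FALSE, seed = 1L) {
  cfg <- list(editor = editor, pam = pam,
              windowStart = as.integer(windowStart),
              windowEnd = as.integer(windowEnd), flank = as.integer(flank),
              weightWindow = weightWindow,
              weightTranscript = weightTranscript,
              ddpcrVariant = ddpcrVariant,
              detectionLimitPct = detectionLimitPct,
              includeNoncanonical = isTRUE(includeNoncanonical),
              seed = as.integer(seed))
  ## validate through the profile constructor
  .config_profile(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

.config_profile <- function(cfg) {
  baseEditorProfile(cfg$editor, cfg$pam, cfg$windowStart, cfg$windowEnd)
}

#' @rdname runConfig
#' @param cfg A \code{RunConfig}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(runConfig, raw)
}
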