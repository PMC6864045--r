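## Re-exports so users can work with returned GRanges-based objects without
## attaching the infrastructure packages themselves.

#' @importFrom S4Vectors mcols
#' @export
S4Vectors::mcols

#' @importFrom S4Vectors metadata
#' @export
S4Vectors::metadata

#' @importFrom BiocGenerics start
#' @export
BiocGenerics::start

#' @importFrom BiocGenerics end
#' @export
BiocGenerics::end

#' @importFrom BiocGenerics width
#' @export
BiocGenerics::width
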