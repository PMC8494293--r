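## Generics shared across the package.

#' @export
setGeneric("peakWidth", function(x, ...) standardGeneric("peakWidth"))

#' @export
setGeneric("binProfile", function(x, binSize, ...) standardGeneric("binProfile"))

#' @export
setGeneric("toGRanges", function(x, ...) standardGeneric("toGRanges"))

#' @export
setGeneric("writeBedGraph", function(x, file, ...) standardGeneric("writeBedGraph"))

#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @export
setGeneric("hydrolysisFlux", function(x, ...) standardGeneric("hydrolysisFlux"))
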