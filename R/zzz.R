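#' @keywords internal
#' @importFrom methods new is slot validObject
#' @importFrom utils capture.output
#' @importFrom stats vcov
#' @importFrom Rcpp evalCpp
#' @useDynLib ParBcycle, .registration = TRUE
"_PACKAGE"
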