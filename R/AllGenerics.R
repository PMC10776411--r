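#' @rdname testResults
#' @export
setGeneric("testResults", function(object, ...) standardGeneric("testResults"))

#' @rdname sampleFractions
#' @export
setGeneric("sampleFractions", function(object, ...)
    standardGeneric("sampleFractions"))

#' @rdname biasEstimates
#' @export
setGeneric("biasEstimates", function(object, ...)
    standardGeneric("biasEstimates"))

#' @rdname zeroReport
#' @export
setGeneric("zeroReport", function(object, ...) standardGeneric("zeroReport"))

#' @rdname retainedTaxa
#' @export
setGeneric("retainedTaxa", function(object, ...)
    standardGeneric("retainedTaxa"))
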