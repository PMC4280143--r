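#' @rdname intensityMatrix
#' @export
setGeneric("intensityMatrix", function(x, ...) standardGeneric("intensityMatrix"))

#' @rdname intensityMatrix
#' @export
setGeneric("observedMask", function(x, ...) standardGeneric("observedMask"))

#' @rdname intensityMatrix
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))

#' @rdname designAccessors
#' @export
setGeneric("designFactors", function(x) standardGeneric("designFactors"))

#' @rdname designAccessors
#' @export
setGeneric("primaryFactor", function(x) standardGeneric("primaryFactor"))

#' @rdname designAccessors
#' @export
setGeneric("sampleCovariates", function(x) standardGeneric("sampleCovariates"))

#' @rdname residualMatrix
#' @export
setGeneric("residualMatrix", function(object, ...) standardGeneric("residualMatrix"))

#' @rdname decomposeResiduals
#' @export
setGeneric("decomposeResiduals", function(object, ...) standardGeneric("decomposeResiduals"))

#' @rdname permutationTrendTest
#' @export
setGeneric("permutationTrendTest",
    function(object, B = 500L, alpha = 0.05, seed = NULL, hMax = NULL, ...)
        standardGeneric("permutationTrendTest"))

#' @rdname trendAccessors
#' @export
setGeneric("trendMatrix", function(object) standardGeneric("trendMatrix"))

#' @rdname trendAccessors
#' @export
setGeneric("varianceExplained", function(object) standardGeneric("varianceExplained"))

#' @rdname trendAccessors
#' @export
setGeneric("nTrends", function(object) standardGeneric("nTrends"))

#' @rdname trendAccessors
#' @export
setGeneric("trendPValues", function(object) standardGeneric("trendPValues"))

#' @rdname normAccessors
#' @export
setGeneric("normalizedTable", function(object) standardGeneric("normalizedTable"))

#' @rdname normAccessors
#' @export
setGeneric("trendLoadings", function(object) standardGeneric("trendLoadings"))

#' @rdname normAccessors
#' @export
setGeneric("featureStatus", function(object) standardGeneric("featureStatus"))
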