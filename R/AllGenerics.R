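#' @rdname SimulationTruth-class
#' @param object,x an object.
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))

#' @rdname SimulationTruth-class
#' @export
setGeneric("trueKrel", function(object) standardGeneric("trueKrel"))

#' @rdname SimulationTruth-class
#' @export
setGeneric("poolWeights", function(object) standardGeneric("poolWeights"))

#' @rdname RelRateTable-class
#' @export
setGeneric("krel", function(object) standardGeneric("krel"))

#' @rdname RelRateTable-class
#' @export
setGeneric("krelSE", function(object) standardGeneric("krelSE"))

#' @rdname RelRateTable-class
#' @export
setGeneric("referenceVariant", function(object) standardGeneric("referenceVariant"))

#' @rdname SpecificityModel-class
#' @export
setGeneric("mainEffects", function(object) standardGeneric("mainEffects"))

#' @rdname SpecificityModel-class
#' @export
setGeneric("interactionTerms", function(object) standardGeneric("interactionTerms"))
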