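#' Accessors for spikeTempo classes
#'
#' Small accessor generics so that slots are never reached into directly.
#'
#' @param object an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stimValues", function(object) standardGeneric("stimValues"))

#' @rdname accessors
#' @export
setGeneric("stimComponents", function(object) standardGeneric("stimComponents"))

#' @rdname accessors
#' @export
setGeneric("cleanTarget", function(object) standardGeneric("cleanTarget"))

#' @rdname accessors
#' @export
setGeneric("timeStep", function(object) standardGeneric("timeStep"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("spikeMatrix", function(object) standardGeneric("spikeMatrix"))

#' @rdname accessors
#' @export
setGeneric("layerLabel", function(object) standardGeneric("layerLabel"))

#' @rdname accessors
#' @export
setGeneric("layerSizes", function(object) standardGeneric("layerSizes"))

#' @rdname accessors
#' @export
setGeneric("networkWeights", function(object) standardGeneric("networkWeights"))

#' @rdname accessors
#' @export
setGeneric("binTensor", function(object) standardGeneric("binTensor"))

#' @rdname accessors
#' @export
setGeneric("alignedStimulus", function(object) standardGeneric("alignedStimulus"))

#' @rdname accessors
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))

#' @rdname accessors
setMethod("stimValues", "Stimulus", function(object) object@values)

#' @rdname accessors
setMethod("stimComponents", "Stimulus", function(object) object@components)

#' @rdname accessors
setMethod("cleanTarget", "Stimulus", function(object) {
  if (is.null(object@clean)) object@values else object@clean
})

#' @rdname accessors
setMethod("timeStep", "Stimulus", function(object) object@dt)

#' @rdname accessors
setMethod("nChannels", "Stimulus", function(object) ncol(object@values))

#' @rdname accessors
setMethod("spikeMatrix", "SpikeRaster", function(object) object@spikes)

#' @rdname accessors
setMethod("layerLabel", "SpikeRaster", function(object) object@label)

#' @rdname accessors
setMethod("layerSizes", "SpikeNetwork", function(object) object@layerSizes)

#' @rdname accessors
setMethod("networkWeights", "SpikeNetwork", function(object) object@weights)

#' @rdname accessors
setMethod("binTensor", "BinnedResponse", function(object) object@tensor)

#' @rdname accessors
setMethod("alignedStimulus", "BinnedResponse", function(object) object@alignedStimulus)

#' @rdname accessors
setMethod("curveValues", "InformationCurve", function(object) object@values)
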