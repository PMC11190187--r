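# Generics for the package's S4 containers.

#' @rdname Recording-class
#' @param object,x an object.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname Recording-class
#' @export
setGeneric("wordOffsets", function(object) standardGeneric("wordOffsets"))

#' @rdname Recording-class
#' @export
setGeneric("recordingData", function(object) standardGeneric("recordingData"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))

#' @rdname EpochSet-class
#' @export
setGeneric("tokenIds", function(object) standardGeneric("tokenIds"))

#' @rdname EpochSet-class
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname GammaMixtureFit-class
#' @param fit a [GammaMixtureFit-class] object.
#' @export
setGeneric("mixtureBoundary", function(fit, ...) standardGeneric("mixtureBoundary"))

#' @rdname GammaMixtureFit-class
#' @export
setGeneric("mixtureParameters", function(fit) standardGeneric("mixtureParameters"))

#' @rdname SvdReduction-class
#' @export
setGeneric("reductionBasis", function(object) standardGeneric("reductionBasis"))

#' @rdname SvdReduction-class
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname SplitDesign-class
#' @export
setGeneric("trainIds", function(object) standardGeneric("trainIds"))

#' @rdname SplitDesign-class
#' @param set one of `"neutral"`, `"coherent"`, `"incoherent"`.
#' @export
setGeneric("testIds", function(object, set) standardGeneric("testIds"))
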