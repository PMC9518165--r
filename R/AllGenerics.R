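# Accessor generics and methods. Slot access from user code should go through
# these rather than @.

#' @name accessors
#' @title Accessors for laughcep S4 classes
#' @param object an S4 object from this package.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "AudioClip", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioClip", function(object) object@sampleRate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "SpectrogramFrames", function(object) object@sampleRate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "FilterBank", function(object) object@sampleRate)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "AudioClip", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setMethod("classLabel", "AudioClip", function(object) object@classLabel)
#' @rdname accessors
#' @export
setMethod("classLabel", "CohortModel", function(object) object@classLabel)

#' @rdname accessors
#' @export
setGeneric("sexLabel", function(object) standardGeneric("sexLabel"))
#' @rdname accessors
#' @export
setMethod("sexLabel", "AudioClip", function(object) object@sex)
#' @rdname accessors
#' @export
setMethod("sexLabel", "CohortModel", function(object) object@sex)

#' @rdname accessors
#' @export
setGeneric("clipId", function(object) standardGeneric("clipId"))
#' @rdname accessors
#' @export
setMethod("clipId", "AudioClip", function(object) object@clipId)

#' Duration of a clip in seconds
#' @param object an [AudioClip-class].
#' @return length of the waveform divided by its sample rate.
#' @export
setGeneric("durationSec", function(object) standardGeneric("durationSec"))
#' @rdname durationSec
#' @export
setMethod("durationSec", "AudioClip",
          function(object) length(object@samples) / object@sampleRate)

#' @rdname accessors
#' @export
setGeneric("powerMatrix", function(object) standardGeneric("powerMatrix"))
#' @rdname accessors
#' @export
setMethod("powerMatrix", "SpectrogramFrames", function(object) object@power)

#' @rdname accessors
#' @export
setGeneric("binHz", function(object) standardGeneric("binHz"))
#' @rdname accessors
#' @export
setMethod("binHz", "SpectrogramFrames", function(object) object@binHz)

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setMethod("frameTimes", "SpectrogramFrames", function(object) object@frameTimes)

#' @rdname accessors
#' @export
setGeneric("bankKind", function(object) standardGeneric("bankKind"))
#' @rdname accessors
#' @export
setMethod("bankKind", "FilterBank", function(object) object@kind)
#' @rdname accessors
#' @export
setMethod("bankKind", "CepstralTrack", function(object) object@bankKind)

#' @rdname accessors
#' @export
setGeneric("centersHz", function(object) standardGeneric("centersHz"))
#' @rdname accessors
#' @export
setMethod("centersHz", "FilterBank", function(object) object@centersHz)

#' @rdname accessors
#' @export
setGeneric("bankWeights", function(object) standardGeneric("bankWeights"))
#' @rdname accessors
#' @export
setMethod("bankWeights", "FilterBank", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("nFilters", function(object) standardGeneric("nFilters"))
#' @rdname accessors
#' @export
setMethod("nFilters", "FilterBank", function(object) length(object@centersHz))

#' @rdname accessors
#' @export
setGeneric("filterEdges", function(object) standardGeneric("filterEdges"))
#' @rdname accessors
#' @export
setMethod("filterEdges", "FilterBank", function(object) {
  data.frame(filter = seq_along(object@centersHz), lower_hz = object@lowerHz,
             center_hz = object@centersHz, upper_hz = object@upperHz)
})

#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(object) standardGeneric("coefMatrix"))
#' @rdname accessors
#' @export
setMethod("coefMatrix", "CepstralTrack", function(object) object@coef)

#' @rdname accessors
#' @export
setGeneric("deltaMatrix", function(object) standardGeneric("deltaMatrix"))
#' @rdname accessors
#' @export
setMethod("deltaMatrix", "CepstralTrack", function(object) object@delta)

#' @rdname accessors
#' @export
setGeneric("delta2Matrix", function(object) standardGeneric("delta2Matrix"))
#' @rdname accessors
#' @export
setMethod("delta2Matrix", "CepstralTrack", function(object) object@delta2)

#' Length of the feature vector implied by a selection
#' @param object a [FeatureSelection-class].
#' @param nCoeffs coefficients per stream (default 13).
#' @return integer vector length (13 x streams x moments by default).
#' @export
setGeneric("featureLength",
           function(object, nCoeffs = 13L) standardGeneric("featureLength"))
#' @rdname featureLength
#' @export
setMethod("featureLength", "FeatureSelection", function(object, nCoeffs = 13L) {
  as.integer(nCoeffs) * length(object@streams) * length(object@moments)
})

#' @rdname accessors
#' @export
setGeneric("cohortMean", function(object) standardGeneric("cohortMean"))
#' @rdname accessors
#' @export
setMethod("cohortMean", "CohortModel", function(object) {
  structure(object@mean, names = if (length(object@featureNames))
    object@featureNames else NULL)
})

#' @rdname accessors
#' @export
setGeneric("cohortVariance", function(object) standardGeneric("cohortVariance"))
#' @rdname accessors
#' @export
setMethod("cohortVariance", "CohortModel", function(object) {
  structure(object@variance, names = if (length(object@featureNames))
    object@featureNames else NULL)
})

#' @rdname accessors
#' @export
setGeneric("arPercent", function(object) standardGeneric("arPercent"))
#' @rdname accessors
#' @export
setMethod("arPercent", "EvalReport", function(object) object@arPercent)

#' @rdname accessors
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setMethod("aucValue", "EvalReport", function(object) object@auc)

#' @rdname accessors
#' @export
setGeneric("mccValue", function(object) standardGeneric("mccValue"))
#' @rdname accessors
#' @export
setMethod("mccValue", "EvalReport", function(object) object@mcc)

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setMethod("rocPoints", "EvalReport", function(object) object@rocPoints)

#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))
#' @rdname accessors
#' @export
setMethod("foldAssignment", "CVPlan", function(object) object@foldAssignment)
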