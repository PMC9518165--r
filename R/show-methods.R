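setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip '%s' (%.3f s @ %g Hz)\n", object@clipId,
              durationSec(object), object@sampleRate))
  cat(sprintf("  subject: %s | class: %s | sex: %s\n",
              object@subjectId, object@classLabel, object@sex))
  cat(sprintf("  amplitude range: [%.3f, %.3f]\n",
              min(object@samples), max(object@samples)))
})

setMethod("show", "FramingConfig", function(object) {
  hop <- object@windowMs - object@overlapMs
  cat(sprintf("FramingConfig: %g ms %s windows, %g ms overlap (hop %g ms),\n",
              object@windowMs, object@windowShape, object@overlapMs, hop))
  cat(sprintf("  pre-emphasis k = %g, DFT size = %d\n",
              object@preemphK, object@dftSize))
})

setMethod("show", "SpectrogramFrames", function(object) {
  cat(sprintf("SpectrogramFrames: %d frames x %d bins (0-%g Hz, DFT %d @ %g Hz)\n",
              nrow(object@power), ncol(object@power), max(object@binHz),
              object@dftSize, object@sampleRate))
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank '%s': %d triangular filters on %g Hz / %d-point grid\n",
              object@kind, nFilters(object), object@sampleRate, object@dftSize))
  cat(sprintf("  centres: %.2f ... %.2f Hz\n",
              object@centersHz[1], object@centersHz[nFilters(object)]))
})

setMethod("show", "CepstralTrack", function(object) {
  cat(sprintf("CepstralTrack (%s): %d frames x %d coefficients (+delta, +delta-delta)\n",
              object@bankKind, nrow(object@coef), ncol(object@coef)))
})

setMethod("show", "FeatureSelection", function(object) {
  cat(sprintf("FeatureSelection: streams {%s} x moments {%s} -> %d components\n",
              paste(object@streams, collapse = ","),
              paste(object@moments, collapse = ","), featureLength(object)))
})

setMethod("show", "CohortModel", function(object) {
  cat(sprintf("CohortModel (%s/%s): %d components, fitted on %d laughs\n",
              object@classLabel, object@sex, length(object@mean), object@nSource))
  cat(sprintf("  covariance: %s\n",
              if (is.null(object@covariance)) "diagonal" else "full"))
})

setMethod("show", "ClassifierSpec", function(object) {
  extra <- switch(object@family,
    rf  = sprintf("%d trees", object@rfTrees),
    knn = sprintf("k = %d", object@knnK),
    svm = sprintf("kernel = %s, nu = %g", object@svmKernel, object@svmNu))
  cat(sprintf("ClassifierSpec: %s (%s), standardize = %s, seed = %d\n",
              object@family, extra, object@standardize, object@seed))
})

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: %d folds over %d groups\n",
              object@kFolds, length(object@foldAssignment)))
})

setMethod("show", "EvalReport", function(object) {
  cat("Cross-validated evaluation (pooled out-of-fold predictions)\n")
  cat(sprintf("  AR = %.1f%%  MCC = %.3f  AUC = %.3f\n",
              object@arPercent, object@mcc, object@auc))
  cat(sprintf("  TPR = %.3f  FPR = %.3f  TNR = %.3f  FNR = %.3f\n",
              object@tpRate, object@fpRate, object@tnRate, object@fnRate))
  cat(sprintf("  sensitivity = %.3f  specificity = %.3f  (n = %d)\n",
              object@sensitivity, object@specificity, nrow(object@predictions)))
})
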