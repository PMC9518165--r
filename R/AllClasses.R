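#' @import methods
#' @importFrom stats fft rnorm runif sd var approx
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' AudioClip: a labelled mono waveform
#'
#' Container for a single laugh bout: a mono amplitude sequence in
#' \code{[-1, 1]} together with its sample rate and the metadata carried
#' through the pipeline (subject, class, sex, clip id).
#'
#' @slot samples numeric vector of amplitudes, nominally in \code{[-1, 1]}.
#' @slot sampleRate sampling rate in Hz.
#' @slot subjectId opaque subject label.
#' @slot classLabel one of \code{"healthy"}, \code{"pd"} or \code{"unknown"}.
#' @slot sex one of \code{"m"}, \code{"f"} or \code{"unknown"}.
#' @slot clipId opaque clip label.
#'
#' @exportClass AudioClip
setClass("AudioClip",
  representation(
    samples    = "numeric",
    sampleRate = "numeric",
    subjectId  = "character",
    classLabel = "character",
    sex        = "character",
    clipId     = "character"
  ),
  prototype(
    subjectId = "unknown", classLabel = "unknown",
    sex = "unknown", clipId = "unknown"
  )
)

setValidity("AudioClip", function(object) {
  msg <- NULL
  if (length(object@samples) < 1L) msg <- c(msg, "samples must be non-empty")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0) {
    msg <- c(msg, "sampleRate must be a single positive number")
  }
  if (anyNA(object@samples)) msg <- c(msg, "samples contain NA")
  if (!object@classLabel %in% c("healthy", "pd", "unknown")) {
    msg <- c(msg, "classLabel must be 'healthy', 'pd' or 'unknown'")
  }
  if (!object@sex %in% c("m", "f", "unknown")) {
    msg <- c(msg, "sex must be 'm', 'f' or 'unknown'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an AudioClip
#'
#' @param samples numeric amplitude vector.
#' @param sampleRate sampling rate in Hz.
#' @param subjectId,classLabel,sex,clipId metadata labels.
#' @return An [AudioClip-class] object.
#' @examples
#' clip <- AudioClip(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)), 16000)
#' durationSec(clip)
#' @export
AudioClip <- function(samples, sampleRate, subjectId = "unknown",
                      classLabel = "unknown", sex = "unknown",
                      clipId = "unknown") {
  new("AudioClip", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate),
      subjectId = as.character(subjectId),
      classLabel = as.character(classLabel),
      sex = as.character(sex), clipId = as.character(clipId))
}

#' FramingConfig: short-time analysis parameters
#'
#' Parameters of the short-time front end: window length and inter-window
#' overlap in milliseconds, pre-emphasis coefficient, and DFT size. The
#' defaults are 25 ms Hanning windows with 10 ms overlap (hence a 15 ms hop),
#' pre-emphasis k = 0.97 and a 512-point DFT at 16 kHz.
#'
#' @slot windowMs window duration (ms).
#' @slot overlapMs inter-window overlap (ms); must be less than `windowMs`.
#' @slot preemphK pre-emphasis coefficient in (0, 1).
#' @slot dftSize DFT length (samples); must be at least the window length.
#' @slot windowShape currently only `"hanning"`.
#'
#' @exportClass FramingConfig
setClass("FramingConfig",
  representation(
    windowMs    = "numeric",
    overlapMs   = "numeric",
    preemphK    = "numeric",
    dftSize     = "integer",
    windowShape = "character"
  )
)

setValidity("FramingConfig", function(object) {
  msg <- NULL
  if (object@windowMs <= 0) msg <- c(msg, "windowMs must be positive")
  if (object@overlapMs <= 0 || object@overlapMs >= object@windowMs) {
    msg <- c(msg, "overlapMs must satisfy 0 < overlapMs < windowMs")
  }
  if (object@preemphK <= 0 || object@preemphK >= 1) {
    msg <- c(msg, "preemphK must lie strictly in (0, 1)")
  }
  if (object@dftSize < 1L) msg <- c(msg, "dftSize must be positive")
  if (!identical(object@windowShape, "hanning")) {
    msg <- c(msg, "windowShape must be 'hanning'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a FramingConfig
#'
#' @param windowMs window duration in ms (default 25).
#' @param overlapMs inter-window overlap in ms (default 10). Note this is the
#'   overlap, not the hop: the hop is `windowMs - overlapMs`.
#' @param preemphK pre-emphasis coefficient in (0, 1) (default 0.97).
#' @param dftSize DFT length in samples (default 512).
#' @param windowShape analysis window shape; only `"hanning"`.
#' @return A [FramingConfig-class] object.
#' @export
FramingConfig <- function(windowMs = 25, overlapMs = 10, preemphK = 0.97,
                          dftSize = 512L, windowShape = "hanning") {
  new("FramingConfig", windowMs = windowMs, overlapMs = overlapMs,
      preemphK = preemphK, dftSize = as.integer(dftSize),
      windowShape = windowShape)
}

#' SpectrogramFrames: per-frame power spectra
#'
#' @slot power T x (dftSize/2 + 1) matrix of non-negative power per DFT bin.
#' @slot binHz centre frequency (Hz) of each retained DFT bin.
#' @slot frameTimes start time (s) of each frame.
#' @slot sampleRate sampling rate (Hz) of the source clip.
#' @slot dftSize DFT length used.
#'
#' @exportClass SpectrogramFrames
setClass("SpectrogramFrames",
  representation(
    power      = "matrix",
    binHz      = "numeric",
    frameTimes = "numeric",
    sampleRate = "numeric",
    dftSize    = "integer"
  )
)

setValidity("SpectrogramFrames", function(object) {
  msg <- NULL
  if (nrow(object@power) < 1L) msg <- c(msg, "at least one frame required")
  if (ncol(object@power) != object@dftSize %/% 2L + 1L) {
    msg <- c(msg, "power must have dftSize/2 + 1 columns")
  }
  if (length(object@binHz) != ncol(object@power)) {
    msg <- c(msg, "binHz length must match power columns")
  }
  if (length(object@frameTimes) != nrow(object@power)) {
    msg <- c(msg, "frameTimes length must match power rows")
  }
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' FilterBank: a triangular auditory filter bank
#'
#' A bank of triangular band-pass filters on the DFT bin grid. Three kinds
#' are supported: `"mel"` (centres equally spaced on the Mel scale), `"bfcc"`
#' (Bark scale spacing) and `"hfcc"` (Mel spacing with per-filter bandwidth
#' set from the equivalent rectangular bandwidth at the centre).
#'
#' @slot kind one of `"mel"`, `"hfcc"`, `"bfcc"`.
#' @slot centersHz per-filter centre frequencies (Hz), strictly increasing.
#' @slot lowerHz,upperHz per-filter triangle edges (Hz).
#' @slot weights M x (dftSize/2 + 1) matrix of triangular responses in [0, 1].
#' @slot sampleRate,dftSize design grid.
#'
#' @exportClass FilterBank
setClass("FilterBank",
  representation(
    kind       = "character",
    centersHz  = "numeric",
    lowerHz    = "numeric",
    upperHz    = "numeric",
    weights    = "matrix",
    sampleRate = "numeric",
    dftSize    = "integer"
  )
)

setValidity("FilterBank", function(object) {
  msg <- NULL
  if (!object@kind %in% c("mel", "hfcc", "bfcc")) {
    msg <- c(msg, "kind must be 'mel', 'hfcc' or 'bfcc'")
  }
  m <- length(object@centersHz)
  if (m < 1L) msg <- c(msg, "at least one filter required")
  if (is.unsorted(object@centersHz, strictly = TRUE)) {
    msg <- c(msg, "centersHz must be strictly increasing")
  }
  if (nrow(object@weights) != m) msg <- c(msg, "weights rows must equal n filters")
  if (ncol(object@weights) != object@dftSize %/% 2L + 1L) {
    msg <- c(msg, "weights must have dftSize/2 + 1 columns")
  }
  if (any(object@weights < 0) || any(object@weights > 1 + 1e-12)) {
    msg <- c(msg, "weights must lie in [0, 1]")
  }
  if (length(object@lowerHz) != m || length(object@upperHz) != m) {
    msg <- c(msg, "lowerHz/upperHz must have one entry per filter")
  }
  if (is.null(msg)) TRUE else msg
})

#' CepstralTrack: per-frame cepstra with dynamics
#'
#' @slot coef T x N matrix of cepstral coefficients (N = 13 by default).
#' @slot delta first-order dynamics (same shape).
#' @slot delta2 second-order dynamics (same shape).
#' @slot bankKind filter-bank kind the cepstra were computed from.
#'
#' @exportClass CepstralTrack
setClass("CepstralTrack",
  representation(
    coef     = "matrix",
    delta    = "matrix",
    delta2   = "matrix",
    bankKind = "character"
  )
)

setValidity("CepstralTrack", function(object) {
  msg <- NULL
  if (!identical(dim(object@coef), dim(object@delta)) ||
      !identical(dim(object@coef), dim(object@delta2))) {
    msg <- c(msg, "coef, delta, delta2 must share dimensions")
  }
  if (!all(is.finite(object@coef)) || !all(is.finite(object@delta)) ||
      !all(is.finite(object@delta2))) {
    msg <- c(msg, "cepstral values must be finite")
  }
  if (is.null(msg)) TRUE else msg
})

#' FeatureSelection: which streams and moments enter the laugh vector
#'
#' Selects the coefficient streams (static `"c"`, delta `"d"`, delta-delta
#' `"dd"`) and pooled moments (`"mean"`, `"sd"`, `"skew"`, `"kurt"`) that make
#' up a per-laugh feature vector. The full default selection gives the
#' 156-component vector (3 streams x 4 moments x 13 coefficients).
#'
#' @slot streams ordered subset of `c("c", "d", "dd")`.
#' @slot moments ordered subset of `c("mean", "sd", "skew", "kurt")`.
#'
#' @exportClass FeatureSelection
setClass("FeatureSelection",
  representation(streams = "character", moments = "character")
)

setValidity("FeatureSelection", function(object) {
  msg <- NULL
  if (length(object@streams) < 1L ||
      !all(object@streams %in% c("c", "d", "dd")) ||
      anyDuplicated(object@streams)) {
    msg <- c(msg, "streams must be a non-empty subset of c('c','d','dd')")
  }
  if (length(object@moments) < 1L ||
      !all(object@moments %in% c("mean", "sd", "skew", "kurt")) ||
      anyDuplicated(object@moments)) {
    msg <- c(msg, "moments must be a non-empty subset of c('mean','sd','skew','kurt')")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a FeatureSelection
#'
#' @param streams ordered subset of `c("c", "d", "dd")`.
#' @param moments ordered subset of `c("mean", "sd", "skew", "kurt")`.
#' @return A [FeatureSelection-class].
#' @examples
#' featureLength(FeatureSelection())                  # 156
#' featureLength(FeatureSelection(moments = c("mean", "sd")))  # 78
#' @export
FeatureSelection <- function(streams = c("c", "d", "dd"),
                             moments = c("mean", "sd", "skew", "kurt")) {
  new("FeatureSelection", streams = streams, moments = moments)
}

#' CohortModel: per-group feature moments for MVN augmentation
#'
#' Mean vector and (diagonal) variance of one subject group's laugh feature
#' vectors; the generative model behind multivariate-normal cohort
#' augmentation. A full covariance matrix may optionally be retained.
#'
#' @slot classLabel,sex the group key.
#' @slot mean per-component mean vector.
#' @slot variance per-component variance (diagonal of the covariance).
#' @slot covariance optional full covariance matrix (NULL for diagonal).
#' @slot nSource number of laughs the model was fitted on.
#' @slot featureNames component names, fixing the layout.
#'
#' @exportClass CohortModel
setClass("CohortModel",
  representation(
    classLabel   = "character",
    sex          = "character",
    mean         = "numeric",
    variance     = "numeric",
    covariance   = "matrixOrNULL",
    nSource      = "integer",
    featureNames = "character"
  ),
  prototype(covariance = NULL, nSource = 0L)
)

setValidity("CohortModel", function(object) {
  msg <- NULL
  if (length(object@mean) != length(object@variance)) {
    msg <- c(msg, "mean and variance must have equal length")
  }
  if (any(!is.finite(object@mean)) || any(!is.finite(object@variance))) {
    msg <- c(msg, "mean and variance must be finite")
  }
  if (any(object@variance < 0)) msg <- c(msg, "variance must be non-negative")
  if (length(object@featureNames) &&
      length(object@featureNames) != length(object@mean)) {
    msg <- c(msg, "featureNames length must match mean")
  }
  if (!is.null(object@covariance) &&
      !identical(dim(object@covariance), rep(length(object@mean), 2L))) {
    msg <- c(msg, "covariance must be D x D")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CohortModel directly
#'
#' @param mean,variance numeric vectors of equal length.
#' @param classLabel,sex group key labels.
#' @param covariance optional full covariance matrix.
#' @param nSource number of source laughs (informational).
#' @param featureNames optional component names.
#' @return A [CohortModel-class].
#' @export
CohortModel <- function(mean, variance, classLabel = "unknown",
                        sex = "unknown", covariance = NULL, nSource = 0L,
                        featureNames = character()) {
  if (!length(featureNames) && !is.null(names(mean))) featureNames <- names(mean)
  new("CohortModel", classLabel = classLabel, sex = sex,
      mean = unname(as.numeric(mean)), variance = unname(as.numeric(variance)),
      covariance = covariance, nSource = as.integer(nSource),
      featureNames = as.character(featureNames))
}

#' LaughFeatureSet: a cohort of per-laugh feature vectors
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one column per laugh
#' and one row per feature component. The `features` assay holds the moment
#' vectors; `colData` carries `subject_id`, `class_label`, `sex` and
#' `clip_id`; `rowData` records the layout (`stream`, `statistic`,
#' `coefficient`).
#'
#' @exportClass LaughFeatureSet
setClass("LaughFeatureSet", contains = "SummarizedExperiment")

setValidity("LaughFeatureSet", function(object) {
  msg <- NULL
  if (!"features" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "must contain a 'features' assay")
  }
  need <- c("subject_id", "class_label", "sex", "clip_id")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object)))) {
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  }
  needRow <- c("stream", "statistic", "coefficient")
  if (!all(needRow %in% colnames(SummarizedExperiment::rowData(object)))) {
    msg <- c(msg, paste("rowData must contain:", paste(needRow, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' ClassifierSpec: one classifier configuration
#'
#' @slot family `"rf"`, `"knn"` or `"svm"`.
#' @slot rfTrees number of random-forest trees (default 100, unpruned).
#' @slot knnK neighbourhood size for kNN (1..10 in the reference protocol).
#' @slot svmKernel one of `"linear"`, `"poly3"`, `"rbf"`, `"nu_linear"`,
#'   `"nu_poly3"`, `"nu_rbf"`.
#' @slot svmNu nu parameter of nu-SVC (default 0.5).
#' @slot standardize z-score features by training-fold statistics (applied
#'   to kNN and SVM; ignored by RF).
#' @slot seed integer seed for any stochastic fitting.
#'
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
  representation(
    family      = "character",
    rfTrees     = "integer",
    knnK        = "integer",
    svmKernel   = "character",
    svmNu       = "numeric",
    standardize = "logical",
    seed        = "integer"
  )
)

setValidity("ClassifierSpec", function(object) {
  msg <- NULL
  if (!object@family %in% c("rf", "knn", "svm")) {
    msg <- c(msg, "family must be 'rf', 'knn' or 'svm'")
  }
  if (object@rfTrees < 1L) msg <- c(msg, "rfTrees must be >= 1")
  if (object@knnK < 1L) msg <- c(msg, "knnK must be >= 1")
  kernels <- c("linear", "poly3", "rbf", "nu_linear", "nu_poly3", "nu_rbf")
  if (!object@svmKernel %in% kernels) {
    msg <- c(msg, paste("svmKernel must be one of:", paste(kernels, collapse = ", ")))
  }
  if (object@svmNu <= 0 || object@svmNu >= 1) msg <- c(msg, "svmNu must be in (0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ClassifierSpec
#'
#' @param family `"rf"`, `"knn"` or `"svm"`.
#' @param rfTrees RF tree count (default 100, no pruning).
#' @param knnK kNN neighbourhood size (default 5).
#' @param svmKernel SVM kernel; `nu_*` variants use nu-SVC, others C-SVC.
#' @param svmNu nu-SVC nu (default 0.5).
#' @param standardize z-score by training-fold statistics for kNN/SVM.
#' @param seed integer seed.
#' @return A [ClassifierSpec-class].
#' @export
ClassifierSpec <- function(family = c("rf", "knn", "svm"), rfTrees = 100L,
                           knnK = 5L, svmKernel = "nu_linear", svmNu = 0.5,
                           standardize = TRUE, seed = 1L) {
  new("ClassifierSpec", family = match.arg(family),
      rfTrees = as.integer(rfTrees), knnK = as.integer(knnK),
      svmKernel = svmKernel, svmNu = svmNu,
      standardize = isTRUE(standardize), seed = as.integer(seed))
}

#' CVPlan: a grouped cross-validation plan
#'
#' Maps grouping units (typically subjects) to folds so that all records of
#' one group share a fold.
#'
#' @slot kFolds number of folds.
#' @slot foldAssignment integer fold index named by group label.
#'
#' @exportClass CVPlan
setClass("CVPlan",
  representation(kFolds = "integer", foldAssignment = "integer")
)

setValidity("CVPlan", function(object) {
  msg <- NULL
  if (object@kFolds < 2L) msg <- c(msg, "kFolds must be >= 2")
  if (is.null(names(object@foldAssignment))) {
    msg <- c(msg, "foldAssignment must be named by group")
  }
  if (length(object@foldAssignment) &&
      (min(object@foldAssignment) < 1L ||
       max(object@foldAssignment) > object@kFolds)) {
    msg <- c(msg, "fold indices must lie in 1..kFolds")
  }
  if (is.null(msg)) TRUE else msg
})

#' EvalReport: pooled cross-validated classification metrics
#'
#' Metrics are computed on the pooled out-of-fold predictions: accuracy rate
#' (per cent), per-class confusion rates (TP rate + FN rate = 1 and
#' TN rate + FP rate = 1), sensitivity/specificity, Matthews correlation,
#' and the ROC curve with its trapezoidal AUC.
#'
#' @slot arPercent accuracy rate in per cent.
#' @slot confusion 2 x 2 count matrix (rows truth, cols prediction).
#' @slot tpRate,fpRate,tnRate,fnRate per-class rates.
#' @slot sensitivity,specificity recall of the positive/negative class.
#' @slot mcc Matthews correlation coefficient.
#' @slot rocPoints data.frame of (fpr, tpr) points.
#' @slot auc area under the ROC curve.
#' @slot perFold per-fold accuracy breakdown.
#' @slot predictions pooled out-of-fold predictions with scores.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    arPercent   = "numeric",
    confusion   = "matrix",
    tpRate      = "numeric",
    fpRate      = "numeric",
    tnRate      = "numeric",
    fnRate      = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    mcc         = "numeric",
    rocPoints   = "data.frame",
    auc         = "numeric",
    perFold     = "data.frame",
    predictions = "data.frame"
  )
)
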