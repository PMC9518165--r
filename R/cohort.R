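# Feature-space cohort augmentation: fit per-group moment models and draw
# multivariate-normal laughs from them.

#' Fit a cohort model to one group's feature vectors
#'
#' Per-component sample mean and sample variance (n-1 denominator) of the
#' group's laugh vectors; the diagonal-covariance normal these define is the
#' generative model used for cohort augmentation. Optionally retains the
#' full sample covariance.
#'
#' @param fs a [LaughFeatureSet-class].
#' @param classLabel group class (`"healthy"` or `"pd"`); `NULL` pools all.
#' @param sex group sex (`"m"`, `"f"`); `NULL` pools both sexes.
#' @param fullCov retain the full sample covariance matrix (default FALSE;
#'   sampling stays diagonal unless the model carries a covariance).
#' @return A [CohortModel-class].
#' @export
fitCohortModel <- function(fs, classLabel = NULL, sex = NULL, fullCov = FALSE) {
  cd <- SummarizedExperiment::colData(fs)
  keep <- rep(TRUE, ncol(fs))
  if (!is.null(classLabel)) keep <- keep & cd$class_label == classLabel
  if (!is.null(sex)) keep <- keep & cd$sex == sex
  mat <- SummarizedExperiment::assay(fs, "features")[, keep, drop = FALSE]
  if (ncol(mat) < 2L) {
    stop("at least 2 laughs are required to fit a cohort model")
  }
  x <- t(mat)
  CohortModel(
    mean = colMeans(x),
    variance = apply(x, 2L, stats::var),
    classLabel = classLabel %||% "unknown",
    sex = sex %||% "unknown",
    covariance = if (fullCov) stats::cov(x) else NULL,
    nSource = ncol(mat),
    featureNames = rownames(mat))
}

#' Sample laughs from a cohort model
#'
#' Independent draws from the normal the model defines: diagonal covariance
#' by default, or the full covariance if the model carries one (Cholesky
#' factorisation). Reproducible for a given seed; the RNG state of the
#' session is left untouched.
#'
#' @param model a [CohortModel-class].
#' @param n number of laughs to draw.
#' @param seed integer seed.
#' @param clipPrefix prefix for the generated clip ids.
#' @return A [LaughFeatureSet-class] with `n` columns labelled by the
#'   model's group.
#' @export
sampleCohort <- function(model, n, seed = 1L, clipPrefix = NULL) {
  if (n < 1L) stop("n must be >= 1")
  D <- length(model@mean)
  draws <- withr::with_seed(as.integer(seed), {
    if (!is.null(model@covariance)) {
      z <- matrix(stats::rnorm(n * D), n, D)
      ch <- chol(model@covariance + diag(1e-12, D))
      sweep(z %*% ch, 2L, model@mean, `+`)
    } else {
      z <- matrix(stats::rnorm(n * D), n, D)
      sweep(sweep(z, 2L, sqrt(model@variance), `*`), 2L, model@mean, `+`)
    }
  })
  mat <- t(draws)
  rownames(mat) <- if (length(model@featureNames)) model@featureNames else
    paste0("f", seq_len(D))
  if (is.null(clipPrefix)) {
    clipPrefix <- paste0("mvn_", model@classLabel, "_", model@sex)
  }
  ids <- sprintf("%s_%05d", clipPrefix, seq_len(n))
  LaughFeatureSet(mat, colData = data.frame(
    subject_id = ids,  # generated laughs have no subject; each is its own group
    class_label = model@classLabel, sex = model@sex, clip_id = ids))
}

#' Sample a multi-group cohort
#'
#' Draws `nPerGroup` laughs from each model and binds them into one set;
#' each model gets a distinct sub-seed derived from `seed`.
#'
#' @param models list of [CohortModel-class] objects.
#' @param nPerGroup draws per model (recycled).
#' @param seed integer seed.
#' @return A [LaughFeatureSet-class].
#' @export
sampleCohorts <- function(models, nPerGroup, seed = 1L) {
  nPerGroup <- rep_len(nPerGroup, length(models))
  sets <- lapply(seq_along(models), function(i) {
    sampleCohort(models[[i]], nPerGroup[i], seed = as.integer(seed) + 1000L * i,
                 clipPrefix = sprintf("mvn%d_%s_%s", i,
                                      models[[i]]@classLabel, models[[i]]@sex))
  })
  do.call(cbindFeatureSets, sets)
}

#' Bind feature sets column-wise
#' @param ... [LaughFeatureSet-class] objects sharing a layout.
#' @return A [LaughFeatureSet-class].
#' @export
cbindFeatureSets <- function(...) {
  new("LaughFeatureSet", do.call(BiocGenerics::cbind, list(...)))
}

#' Write / read cohort models as a tabular file
#'
#' One row per feature component with the group key, mean and variance.
#'
#' @param model a [CohortModel-class].
#' @param path output TSV path.
#' @return `path` invisibly (writer); a [CohortModel-class] (reader).
#' @export
writeCohortModel <- function(model, path) {
  nm <- if (length(model@featureNames)) model@featureNames else
    paste0("f", seq_along(model@mean))
  df <- data.frame(component = nm, mean = model@mean,
                   variance = model@variance,
                   class_label = model@classLabel, sex = model@sex,
                   n_source = model@nSource)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortModel
#' @export
readCohortModel <- function(path) {
  df <- utils::read.delim(path)
  CohortModel(mean = df$mean, variance = df$variance,
              classLabel = df$class_label[1L], sex = df$sex[1L],
              nSource = df$n_source[1L], featureNames = df$component)
}
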