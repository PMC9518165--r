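# Log/DCT cepstra, delta dynamics, and moment pooling into the per-laugh
# feature vector.

#' Cepstral coefficients from filter-bank energies
#'
#' DCT of the log band energies:
#' `c_n = sum_{m=1..M} log10(s(m)) cos(pi n (m - 0.5) / M)`, for
#' `n = 1..nCoeffs`. The `n = 0` term is a pure log-energy sum and is
#' excluded so that coefficients are invariant to global waveform gain.
#' Energies are floored at `floorAt` before the log so silent frames stay
#' finite.
#'
#' @param energies T x M matrix of band energies (from [applyFilterbank()]).
#' @param nCoeffs number of coefficients (default 13); must be `<= M`.
#' @param floorAt energy floor applied before `log10` (default 1e-10).
#' @return T x nCoeffs matrix.
#' @export
cepstraFromEnergies <- function(energies, nCoeffs = 13L, floorAt = 1e-10) {
  energies <- as.matrix(energies)
  M <- ncol(energies)
  nCoeffs <- as.integer(nCoeffs)
  if (nCoeffs > M) stop("nCoeffs must not exceed the number of filters")
  logS <- log10(pmax(energies, floorAt))
  basis <- outer(seq_len(M) - 0.5, seq_len(nCoeffs),
                 function(m, n) cos(pi * n * m / M))
  logS %*% basis
}

#' First-order delta of a coefficient track
#'
#' Central difference across frames, `delta(t) = (c(t+1) - c(t-1)) / 2`,
#' with edge replication (`c(0)` and `c(T+1)` replicate the first and last
#' frames). Applying it twice yields the delta-delta track.
#'
#' @param x T x N coefficient matrix (or vector).
#' @return matrix (or vector) of the same shape.
#' @export
deltaTrack <- function(x) {
  vec <- is.null(dim(x))
  x <- rbind(as.matrix(x))
  TT <- nrow(x)
  prev <- x[pmax(seq_len(TT) - 1L, 1L), , drop = FALSE]
  nxt <- x[pmin(seq_len(TT) + 1L, TT), , drop = FALSE]
  d <- (nxt - prev) / 2
  if (vec) drop(d) else d
}

#' Cepstral track with dynamics from band energies
#'
#' @param energies T x M band-energy matrix.
#' @param nCoeffs number of cepstral coefficients (default 13).
#' @param bankKind label recording the source filter bank.
#' @param floorAt energy floor before `log10`.
#' @return A [CepstralTrack-class] with static, delta and delta-delta
#'   matrices.
#' @export
cepstralTrack <- function(energies, nCoeffs = 13L, bankKind = "mel",
                          floorAt = 1e-10) {
  cc <- cepstraFromEnergies(energies, nCoeffs, floorAt)
  d <- deltaTrack(cc)
  new("CepstralTrack", coef = cc, delta = d, delta2 = deltaTrack(d),
      bankKind = bankKind)
}

# pooled sample statistics for one column; sd uses the n-1 denominator,
# skewness m3/m2^1.5 and (non-excess) kurtosis m4/m2^2 use population
# moments. Zero-variance columns get skew = kurt = 0 by convention.
.momentStats <- function(x) {
  n <- length(x)
  mu <- mean(x)
  s <- if (n > 1L) stats::sd(x) else 0
  m2 <- mean((x - mu)^2)
  if (m2 <= .Machine$double.eps * max(1, mu^2)) {
    c(mean = mu, sd = 0, skew = 0, kurt = 0)
  } else {
    c(mean = mu, sd = s,
      skew = mean((x - mu)^3) / m2^1.5,
      kurt = mean((x - mu)^4) / m2^2)
  }
}

#' Feature layout names for a selection
#'
#' Component names of the pooled vector in its fixed order: streams
#' outermost, then moments, then coefficient index, e.g. `c.mean.1`,
#' ..., `dd.kurt.13`.
#'
#' @param sel a [FeatureSelection-class].
#' @param nCoeffs coefficients per stream.
#' @return character vector of length [featureLength()].
#' @export
featureLayout <- function(sel, nCoeffs = 13L) {
  unlist(lapply(sel@streams, function(s)
    lapply(sel@moments, function(m)
      paste(s, m, seq_len(nCoeffs), sep = "."))))
}

#' Pool per-frame cepstra into a per-laugh moment vector
#'
#' For every selected stream (static, delta, delta-delta) and coefficient,
#' computes the selected moments over the T frames: sample mean, sample SD
#' (n-1 denominator), skewness and non-excess kurtosis (a normal column
#' gives kurtosis 3; zero-variance columns give skew = kurt = 0 by
#' convention). Components are assembled in the fixed layout of
#' [featureLayout()]; the full default selection yields 156 components.
#'
#' @param track a [CepstralTrack-class].
#' @param sel a [FeatureSelection-class].
#' @return named numeric vector.
#' @export
poolMoments <- function(track, sel = FeatureSelection()) {
  mats <- list(c = track@coef, d = track@delta, dd = track@delta2)
  TT <- nrow(track@coef)
  if (TT < 2L && any(sel@moments != "mean")) {
    stop("at least 2 frames are required for SD/skew/kurt pooling")
  }
  out <- unlist(lapply(sel@streams, function(s) {
    stat <- apply(mats[[s]], 2L, .momentStats)  # 4 x nCoeffs
    unlist(lapply(sel@moments, function(m) stat[m, ]))
  }))
  names(out) <- featureLayout(sel, ncol(track@coef))
  out
}

#' Extract the per-laugh feature vector from a clip
#'
#' Deterministic composition of the whole front end: pre-emphasis, Hanning
#' framing, power spectra, filter-bank energies, log/DCT cepstra, delta and
#' delta-delta dynamics, moment pooling.
#'
#' @param clip an [AudioClip-class].
#' @param cfg a [FramingConfig-class].
#' @param bank a [FilterBank-class].
#' @param sel a [FeatureSelection-class].
#' @param nCoeffs cepstral coefficients per stream (default 13).
#' @return named numeric vector with attributes `subject_id`, `class_label`,
#'   `sex`, `clip_id` copied from the clip.
#' @export
extractFeatures <- function(clip, cfg = FramingConfig(),
                            bank = buildFilterbank("mel"),
                            sel = FeatureSelection(), nCoeffs = 13L) {
  spec <- clipSpectrogram(clip, cfg)
  energies <- applyFilterbank(spec, bank)
  track <- cepstralTrack(energies, nCoeffs, bankKind(bank))
  v <- poolMoments(track, sel)
  attr(v, "subject_id") <- subjectId(clip)
  attr(v, "class_label") <- classLabel(clip)
  attr(v, "sex") <- sexLabel(clip)
  attr(v, "clip_id") <- clipId(clip)
  v
}

#' Assemble a LaughFeatureSet from per-laugh vectors
#'
#' @param vectors list of named vectors from [extractFeatures()], or a
#'   features matrix (components x laughs).
#' @param colData optional data.frame with `subject_id`, `class_label`,
#'   `sex`, `clip_id` (one row per laugh); taken from vector attributes if
#'   absent.
#' @return A [LaughFeatureSet-class].
#' @export
LaughFeatureSet <- function(vectors, colData = NULL) {
  if (is.list(vectors)) {
    mat <- do.call(cbind, lapply(vectors, as.numeric))
    rownames(mat) <- names(vectors[[1L]])
    if (is.null(colData)) {
      colData <- do.call(rbind, lapply(vectors, function(v) {
        data.frame(
          subject_id = attr(v, "subject_id") %||% "unknown",
          class_label = attr(v, "class_label") %||% "unknown",
          sex = attr(v, "sex") %||% "unknown",
          clip_id = attr(v, "clip_id") %||% "unknown")
      }))
    }
  } else {
    mat <- as.matrix(vectors)
    if (is.null(colData)) {
      colData <- data.frame(
        subject_id = paste0("s", seq_len(ncol(mat))),
        class_label = "unknown", sex = "unknown",
        clip_id = paste0("clip", seq_len(ncol(mat))))
    }
  }
  colnames(mat) <- colData$clip_id <- make.unique(as.character(colData$clip_id))
  layout <- .parseLayout(rownames(mat))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = layout,
    colData = S4Vectors::DataFrame(colData))
  new("LaughFeatureSet", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parseLayout <- function(nm) {
  if (is.null(nm)) stop("feature vectors must be named (stream.statistic.coefficient)")
  parts <- strsplit(nm, ".", fixed = TRUE)
  ok <- lengths(parts) == 3L
  if (!all(ok)) stop("feature names must have the form stream.statistic.coefficient")
  S4Vectors::DataFrame(
    stream = vapply(parts, `[[`, "", 1L),
    statistic = vapply(parts, `[[`, "", 2L),
    coefficient = as.integer(vapply(parts, `[[`, "", 3L)),
    row.names = nm)
}

#' Extract a feature set from many clips
#'
#' @param clips list of [AudioClip-class] objects.
#' @param cfg,bank,sel,nCoeffs passed to [extractFeatures()].
#' @return A [LaughFeatureSet-class] with one column per clip.
#' @export
extractFeatureSet <- function(clips, cfg = FramingConfig(),
                              bank = buildFilterbank("mel"),
                              sel = FeatureSelection(), nCoeffs = 13L) {
  LaughFeatureSet(lapply(clips, extractFeatures, cfg = cfg, bank = bank,
                         sel = sel, nCoeffs = nCoeffs))
}

#' Write / read a feature table as CSV
#'
#' One row per laugh; metadata columns (`subject_id`, `class_label`, `sex`,
#' `clip_id`) followed by the feature components named
#' `stream.statistic.coefficient`. The round trip is lossless up to CSV
#' numeric formatting (values are written at full double precision).
#'
#' @param fs a [LaughFeatureSet-class].
#' @param path output CSV path.
#' @return `path` invisibly (writer); a [LaughFeatureSet-class] (reader).
#' @export
writeFeatureTable <- function(fs, path) {
  mat <- SummarizedExperiment::assay(fs, "features")
  cd <- as.data.frame(SummarizedExperiment::colData(fs))
  df <- cbind(cd[, c("subject_id", "class_label", "sex", "clip_id")],
              as.data.frame(t(mat), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("subject_id", "class_label", "sex", "clip_id")
  mat <- t(as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE]))
  LaughFeatureSet(mat, colData = df[, meta, drop = FALSE])
}

#' Subset a feature set to a selection of streams and moments
#'
#' @param fs a [LaughFeatureSet-class].
#' @param sel a [FeatureSelection-class].
#' @return A [LaughFeatureSet-class] restricted to matching rows, in layout
#'   order.
#' @export
selectFeatures <- function(fs, sel) {
  rd <- SummarizedExperiment::rowData(fs)
  keep <- unlist(lapply(sel@streams, function(s)
    lapply(sel@moments, function(m)
      which(rd$stream == s & rd$statistic == m))))
  fs[keep, ]
}
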