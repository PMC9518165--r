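# Autocorrelation pitch tracking and per-clip pitch statistics - the
# negative-control feature set for the pitch-ablation experiment.

#' Per-frame autocorrelation F0 estimates
#'
#' Frames the raw (un-emphasised) waveform into 40 ms windows with 20 ms
#' hop, keeps frames whose energy exceeds `voicedQuantile` of the frame
#' energies, and for each voiced frame picks the lag maximising the
#' normalised autocorrelation inside the plausible F0 band.
#'
#' @param clip an [AudioClip-class].
#' @param fMin,fMax F0 search band in Hz (defaults 75-600, covering adult
#'   laughter).
#' @param frameMs,hopMs analysis geometry.
#' @param voicedQuantile energy quantile separating voiced frames.
#' @return numeric vector of per-frame F0 estimates (Hz) for voiced frames;
#'   attribute `voicedFraction` gives the retained-frame share.
#' @export
trackF0 <- function(clip, fMin = 75, fMax = 600, frameMs = 40, hopMs = 20,
                    voicedQuantile = 0.5) {
  fs <- sampleRate(clip)
  x <- samples(clip)
  W <- round(frameMs / 1000 * fs)
  H <- round(hopMs / 1000 * fs)
  if (length(x) < W) stop("clip shorter than one pitch analysis frame")
  starts <- seq(1L, length(x) - W + 1L, by = H)
  energy <- vapply(starts, function(s) sum(x[s:(s + W - 1L)]^2), numeric(1))
  thr <- stats::quantile(energy, voicedQuantile)
  lagMin <- max(2L, floor(fs / fMax))
  lagMax <- min(W - 1L, ceiling(fs / fMin))
  f0 <- c()
  nVoiced <- 0L
  for (s in starts[energy >= thr & energy > 0]) {
    nVoiced <- nVoiced + 1L
    fr <- x[s:(s + W - 1L)]
    fr <- fr - mean(fr)
    ac <- stats::acf(fr, lag.max = lagMax, plot = FALSE,
                     demean = FALSE)$acf[, 1L, 1L]
    seg <- ac[(lagMin + 1L):(lagMax + 1L)]
    best <- which.max(seg)
    if (seg[best] > 0.25) f0 <- c(f0, fs / (lagMin + best - 1L))
  }
  structure(f0, voicedFraction = nVoiced / length(starts))
}

#' Per-clip pitch statistics
#'
#' Summary of the voiced-frame F0 track: mean, SD, median, min, max, range
#' and voiced fraction. These are the "pitch statistics" used as classifier
#' inputs only in the ablation experiment.
#'
#' @param clip an [AudioClip-class].
#' @param ... passed to [trackF0()].
#' @return named numeric vector (`f0.mean`, `f0.sd`, `f0.median`, `f0.min`,
#'   `f0.max`, `f0.range`, `f0.voiced`), with the clip's metadata attached
#'   as attributes like [extractFeatures()].
#' @export
pitchStats <- function(clip, ...) {
  f0 <- trackF0(clip, ...)
  if (length(f0) < 2L) {
    v <- c(f0.mean = 0, f0.sd = 0, f0.median = 0, f0.min = 0, f0.max = 0,
           f0.range = 0, f0.voiced = 0)
  } else {
    v <- c(f0.mean = mean(f0), f0.sd = stats::sd(f0),
           f0.median = stats::median(f0), f0.min = min(f0), f0.max = max(f0),
           f0.range = max(f0) - min(f0),
           f0.voiced = attr(f0, "voicedFraction"))
  }
  attr(v, "subject_id") <- subjectId(clip)
  attr(v, "class_label") <- classLabel(clip)
  attr(v, "sex") <- sexLabel(clip)
  attr(v, "clip_id") <- clipId(clip)
  v
}
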