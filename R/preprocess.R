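# Short-time front end: clip loading, pre-emphasis, Hanning framing, power
# spectra. Everything downstream (filter banks, cepstra) consumes the
# SpectrogramFrames produced here.

#' Load a laugh clip from a WAV file
#'
#' Reads a PCM WAV file, averages stereo channels to mono, resamples to the
#' target rate with an anti-aliased polyphase filter, and rescales so the
#' peak amplitude does not exceed 1.
#'
#' @param path path to a readable PCM WAV file (mono or stereo).
#' @param targetRate output sample rate in Hz (default 16000, the pipeline
#'   rate; source material is typically 44.1 kHz).
#' @param subjectId,classLabel,sex,clipId metadata attached to the clip; the
#'   default clip id is the file name.
#' @return An [AudioClip-class] at `targetRate`.
#' @export
loadClip <- function(path, targetRate = 16000, subjectId = "unknown",
                     classLabel = "unknown", sex = "unknown",
                     clipId = basename(path)) {
  w <- readWavPcm(path)
  x <- rowMeans(w$samples)
  if (length(x) < 1L) stop("empty audio in ", path)
  if (w$sampleRate != targetRate) {
    g <- .gcd(as.integer(targetRate), as.integer(w$sampleRate))
    x <- as.numeric(signal::resample(x, targetRate %/% g, w$sampleRate %/% g))
  }
  if (length(x) < 1L) stop("clip empty after resampling: ", path)
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  AudioClip(x, targetRate, subjectId = subjectId, classLabel = classLabel,
            sex = sex, clipId = clipId)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Pre-emphasis high-pass filter
#'
#' First-order FIR high-pass `y(n) = x(n) - k x(n-1)` compensating the
#' low-pass spectral tilt of glottal excitation; the first output sample is
#' defined with zero pre-history, `y(0) = x(0)`. Magnitude response is
#' `|1 - k e^{-j w}|`: `1 - k` at DC, `1 + k` at Nyquist.
#'
#' @param clip an [AudioClip-class] (or numeric vector).
#' @param k pre-emphasis coefficient, strictly in (0, 1); 0.95-0.98 is the
#'   usual range and 0.97 the default elsewhere in the package.
#' @return Object of the same type as `clip`, filtered; length preserved.
#' @export
preEmphasize <- function(clip, k = 0.97) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k >= 1) {
    stop("pre-emphasis coefficient k must lie strictly in (0, 1)")
  }
  x <- if (is(clip, "AudioClip")) samples(clip) else as.numeric(clip)
  y <- x - k * c(0, x[-length(x)])
  if (is(clip, "AudioClip")) {
    initialize(clip, samples = y)
  } else {
    y
  }
}

#' Hanning analysis window
#'
#' Symmetric Hanning window `0.5 - 0.5 cos(2 pi n / (W - 1))`, n = 0..W-1.
#'
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @export
hanningWindow <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' Split a clip into overlapping windowed frames
#'
#' Divides the waveform into `windowMs`-long segments whose neighbours
#' overlap by `overlapMs` (so the hop is `windowMs - overlapMs`), discards
#' any trailing partial frame, and multiplies each frame pointwise by a
#' Hanning window. The frame count is `floor((L - W) / H) + 1`.
#'
#' @param clip an [AudioClip-class].
#' @param cfg a [FramingConfig-class].
#' @param window apply the Hanning window (`TRUE`; `FALSE` exposes the raw
#'   frames, used by tests and the pitch tracker).
#' @return T x W numeric matrix of windowed frames, with attributes
#'   `sampleRate` and `frameTimes` (frame start times, s).
#' @export
frameAndWindow <- function(clip, cfg = FramingConfig(), window = TRUE) {
  rate <- sampleRate(clip)
  x <- samples(clip)
  W <- as.integer(round(cfg@windowMs * rate / 1000))
  H <- W - as.integer(round(cfg@overlapMs * rate / 1000))
  if (H < 1L) stop("overlap too close to window length: hop would be < 1 sample")
  if (length(x) < W) {
    stop(sprintf(
      "clip too short for framing: %d samples < one %d-sample (%g ms) window",
      length(x), W, cfg@windowMs))
  }
  if (cfg@dftSize < W) stop("dftSize must be at least the window length")
  nFrames <- (length(x) - W) %/% H + 1L
  starts <- (seq_len(nFrames) - 1L) * H
  idx <- outer(starts, seq_len(W), `+`)
  frames <- matrix(x[idx], nrow = nFrames)
  if (window) {
    frames <- sweep(frames, 2L, hanningWindow(W), `*`)
  }
  attr(frames, "sampleRate") <- rate
  attr(frames, "frameTimes") <- starts / rate
  frames
}

#' Per-frame power spectra
#'
#' Zero-pads each (windowed) frame to `dftSize`, takes the DFT and returns
#' the one-sided power spectrum `|X(j)|^2` for bins `j = 0..dftSize/2`.
#'
#' @param frames T x W frame matrix from [frameAndWindow()].
#' @param cfg a [FramingConfig-class] (supplies `dftSize`).
#' @param sampleRate sample rate in Hz; defaults to the attribute carried by
#'   `frames`.
#' @return A [SpectrogramFrames-class].
#' @export
powerSpectra <- function(frames, cfg = FramingConfig(), sampleRate = NULL) {
  if (is.null(sampleRate)) sampleRate <- attr(frames, "sampleRate")
  if (is.null(sampleRate)) stop("sampleRate not supplied and not carried by frames")
  nfft <- cfg@dftSize
  W <- ncol(frames)
  if (nfft < W) stop("dftSize smaller than frame length")
  padded <- cbind(frames, matrix(0, nrow(frames), nfft - W))
  # mvfft works column-wise
  X <- stats::mvfft(t(padded))
  keep <- seq_len(nfft %/% 2L + 1L)
  power <- t(Mod(X[keep, , drop = FALSE])^2)
  ft <- attr(frames, "frameTimes")
  if (is.null(ft)) ft <- rep(NA_real_, nrow(frames))
  new("SpectrogramFrames",
      power = power,
      binHz = (keep - 1L) * sampleRate / nfft,
      frameTimes = ft,
      sampleRate = as.numeric(sampleRate),
      dftSize = as.integer(nfft))
}

#' Pre-emphasise, frame and transform a clip in one call
#'
#' @param clip an [AudioClip-class].
#' @param cfg a [FramingConfig-class]; its `preemphK` is used.
#' @return A [SpectrogramFrames-class].
#' @export
clipSpectrogram <- function(clip, cfg = FramingConfig()) {
  powerSpectra(frameAndWindow(preEmphasize(clip, cfg@preemphK), cfg), cfg)
}
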