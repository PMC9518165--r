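# Parametric laugh-bout synthesizer. A laugh is a train of voiced "ha"
# bursts: a glottal pulse train with per-cycle jitter (period perturbation)
# and shimmer (amplitude perturbation), shaped by a cascade of vocal-tract
# formant resonators and a per-burst amplitude envelope, separated by aspiration
# gaps, with a breath-noise floor mixed over the whole bout. The healthy ->
# PD-like axis of variation follows the acoustics of hypokinetic dysarthria:
# reduced F0 excursion, raised jitter/shimmer, more breath noise, and
# articulation smearing modelled as widened formant bandwidths.

.healthyParams <- list(f0Var = 0.30, jitter = 0.012, shimmer = 0.06,
                       breathNoiseDb = -28, formantBwScale = 1.0)
.pdParams <- list(f0Var = 0.10, jitter = 0.045, shimmer = 0.18,
                  breathNoiseDb = -13, formantBwScale = 2.4)

#' Laugh synthesis parameters
#'
#' Builds the parameter list for [synthesizeLaugh()]. With
#' `effectSize = 0` the perturbation parameters equal the healthy set
#' exactly; `effectSize = 1` gives the PD-like set; intermediate values
#' interpolate linearly. Any parameter given explicitly overrides the
#' interpolated value.
#'
#' @param nBursts integer range (min, max) of voiced bursts per bout.
#' @param burstDurMs range of burst durations (ms).
#' @param f0Hz base fundamental frequency (Hz) of the bout.
#' @param f0Var relative F0 excursion across and within bursts (healthy
#'   0.30, PD-like 0.10: hypokinetic speech flattens pitch).
#' @param jitter cycle-to-cycle relative F0 perturbation (healthy 0.012,
#'   PD-like 0.045).
#' @param shimmer cycle amplitude perturbation (healthy 0.06, PD-like 0.18).
#' @param breathNoiseDb breath-noise floor relative to the voiced level, dB
#'   (healthy -28, PD-like -13).
#' @param formantBwScale articulation-smearing factor `>= 1` applied to the
#'   formant bandwidths (healthy 1.0, PD-like 2.4).
#' @param effectSize scalar in `[0, 1]` interpolating healthy -> PD-like.
#' @param sampleRate output rate, Hz.
#' @param seed integer seed; synthesis is deterministic given the parameter list.
#' @return a `laughSynthSpec` list.
#' @export
laughSynthSpec <- function(nBursts = c(3L, 6L), burstDurMs = c(120, 260),
                           f0Hz = 250, f0Var = NULL, jitter = NULL,
                           shimmer = NULL, breathNoiseDb = NULL,
                           formantBwScale = NULL, effectSize = 0,
                           sampleRate = 16000, seed = 1L) {
  if (effectSize < 0 || effectSize > 1) stop("effectSize must lie in [0, 1]")
  if (length(nBursts) != 2L || nBursts[2L] < nBursts[1L] || nBursts[1L] < 1L) {
    stop("nBursts must be an increasing range of positive counts")
  }
  if (length(burstDurMs) != 2L || burstDurMs[2L] < burstDurMs[1L] ||
      burstDurMs[1L] <= 0) {
    stop("burstDurMs must be an increasing positive range")
  }
  if (f0Hz <= 0) stop("f0Hz must be positive")
  lerp <- function(name) {
    (1 - effectSize) * .healthyParams[[name]] + effectSize * .pdParams[[name]]
  }
  spec <- list(
    nBursts = as.integer(nBursts), burstDurMs = burstDurMs, f0Hz = f0Hz,
    f0Var = f0Var %||% lerp("f0Var"),
    jitter = jitter %||% lerp("jitter"),
    shimmer = shimmer %||% lerp("shimmer"),
    breathNoiseDb = breathNoiseDb %||% lerp("breathNoiseDb"),
    formantBwScale = formantBwScale %||% lerp("formantBwScale"),
    effectSize = effectSize, sampleRate = sampleRate,
    seed = as.integer(seed))
  if (spec$jitter < 0 || spec$shimmer < 0 || spec$formantBwScale < 1) {
    stop("jitter/shimmer must be >= 0 and formantBwScale >= 1")
  }
  class(spec) <- "laughSynthSpec"
  spec
}

# second-order resonator cascade; r = exp(-pi bw / fs)
.formantFilter <- function(x, freqs, bws, fs) {
  for (i in seq_along(freqs)) {
    r <- exp(-pi * bws[i] / fs)
    theta <- 2 * pi * freqs[i] / fs
    x <- stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive")
    x <- as.numeric(x) * (1 - r)
  }
  x
}

# one voiced burst: glottal pulse train with jitter/shimmer, falling pitch
# contour, attack/decay envelope
.voicedBurst <- function(nSamp, f0, f0Var, jitter, shimmer, fs) {
  src <- numeric(nSamp)
  pos <- 1
  while (pos <= nSamp) {
    frac <- pos / nSamp
    f0t <- f0 * (1 + f0Var * (0.5 - frac))  # pitch falls through the burst
    period <- max(8, round(fs / (f0t * (1 + jitter * stats::rnorm(1)))))
    amp <- max(0, 1 + shimmer * stats::rnorm(1))
    # glottal pulse: half-sine over the open phase (40% of the cycle)
    open <- max(4L, round(0.4 * period))
    idx <- pos:min(nSamp, pos + open - 1L)
    src[idx] <- src[idx] + amp * sin(pi * seq_along(idx) / open)
    pos <- pos + period
  }
  env <- pmax(0, sin(pi * seq_len(nSamp) / nSamp))^0.7  # attack/decay
  src * env
}

#' Synthesize one laugh bout
#'
#' Deterministic for a given spec (all randomness flows through
#' `spec$seed`; the session RNG is untouched).
#'
#' @param spec a [laughSynthSpec()] parameter list.
#' @return An [AudioClip-class] at `spec$sampleRate`, peak-normalised.
#' @export
synthesizeLaugh <- function(spec) {
  if (!inherits(spec, "laughSynthSpec")) stop("spec must come from laughSynthSpec()")
  fs <- spec$sampleRate
  formF <- c(750, 1250, 2600)             # open-vowel "ha" formants
  formB <- c(90, 120, 200) * spec$formantBwScale
  withr::with_seed(spec$seed, {
    nB <- if (spec$nBursts[1L] == spec$nBursts[2L]) spec$nBursts[1L] else
      sample(spec$nBursts[1L]:spec$nBursts[2L], 1L)
    pieces <- vector("list", 2L * nB)
    for (b in seq_len(nB)) {
      dur <- stats::runif(1, spec$burstDurMs[1L], spec$burstDurMs[2L]) / 1000
      f0b <- spec$f0Hz * (1 + spec$f0Var * 0.6 * (stats::runif(1) - 0.5))
      nSamp <- max(32L, round(dur * fs))
      voiced <- .voicedBurst(nSamp, f0b, spec$f0Var, spec$jitter,
                             spec$shimmer, fs)
      pieces[[2L * b - 1L]] <- .formantFilter(voiced, formF, formB, fs)
      gapMs <- stats::runif(1, 60, 140)
      nGap <- round(gapMs / 1000 * fs)
      asp <- stats::rnorm(nGap) * 0.02      # aspiration between bursts
      pieces[[2L * b]] <- .formantFilter(asp, formF, formB, fs)
    }
    x <- unlist(pieces)
    voicedRms <- sqrt(mean(x^2))
    noise <- stats::rnorm(length(x))
    noise <- noise / sqrt(mean(noise^2)) *
      voicedRms * 10^(spec$breathNoiseDb / 20)
    x <- x + noise
    x <- x / max(abs(x)) * 0.9
    AudioClip(x, fs, clipId = sprintf("synth_seed%d", spec$seed))
  })
}

.subSeed <- function(seed, ...) {
  ix <- c(...)
  as.integer((as.double(seed) * 48271 + sum(ix * 7919^seq_along(ix))) %%
               2147483563)
}

#' Simulate a balanced two-class laugh study
#'
#' Generates a class- and sex-balanced cohort of synthetic laugh bouts with
#' subject-level random effects: each subject draws a base F0 (sex-typed)
#' and multiplicative offsets on F0 and burst duration once, so laughs
#' within a subject correlate while subjects differ - the structure that
#' makes subject-wise cross-validation meaningful. PD-class subjects use
#' the parameter set interpolated at `effectSize`.
#'
#' @param nSubjectsPerGroup subjects per class x sex group (4 groups).
#' @param laughsPerSubject laughs recorded per subject.
#' @param effectSize healthy -> PD-like interpolation in `[0, 1]`
#'   (default 0.6).
#' @param seed integer master seed; every clip derives its own sub-seed.
#' @param matchPitch if TRUE the PD class keeps the healthy F0 excursion and
#'   jitter, so the class effect excludes pitch statistics (shimmer, breath
#'   noise and articulation smearing only) - the construction used for the
#'   pitch-ablation negative control.
#' @param sampleRate output rate in Hz.
#' @return list with `clips` (list of [AudioClip-class]) and `manifest`
#'   (data.frame: clip_id, subject_id, class_label, sex, seed).
#' @export
makeSyntheticStudy <- function(nSubjectsPerGroup, laughsPerSubject = 1L,
                               effectSize = 0.6, seed = 1L,
                               matchPitch = FALSE, sampleRate = 16000) {
  if (nSubjectsPerGroup < 1L || laughsPerSubject < 1L) {
    stop("counts must be >= 1")
  }
  groups <- expand.grid(class_label = c("healthy", "pd"), sex = c("f", "m"),
                        stringsAsFactors = FALSE)
  clips <- list()
  rows <- list()
  k <- 0L
  for (g in seq_len(nrow(groups))) {
    cls <- groups$class_label[g]
    sx <- groups$sex[g]
    es <- if (cls == "pd") effectSize else 0
    for (i in seq_len(nSubjectsPerGroup)) {
      sid <- sprintf("%s_%s_s%02d", cls, sx, i)
      subjSeed <- .subSeed(seed, g, i)
      # subject-level random effects: base F0 and burst tempo, plus
      # voice-quality multipliers, so subjects within a class differ and
      # the class distributions overlap
      subj <- withr::with_seed(subjSeed, list(
        f0 = stats::runif(1, if (sx == "f") 220 else 150,
                          if (sx == "f") 320 else 240) *
          exp(0.04 * stats::rnorm(1)),
        durScale = exp(0.10 * stats::rnorm(1)),
        jitterMul = exp(0.55 * stats::rnorm(1)),
        shimmerMul = exp(0.55 * stats::rnorm(1)),
        f0VarMul = exp(0.30 * stats::rnorm(1)),
        noiseAdd = 5.5 * stats::rnorm(1),
        bwMul = exp(0.40 * stats::rnorm(1))))
      base <- lapply(stats::setNames(nm = names(.healthyParams)), function(p) {
        esP <- if (matchPitch && p %in% c("f0Var", "jitter")) 0 else es
        (1 - esP) * .healthyParams[[p]] + esP * .pdParams[[p]]
      })
      for (j in seq_len(laughsPerSubject)) {
        k <- k + 1L
        clipSeed <- .subSeed(seed, g, i, j)
        spec <- laughSynthSpec(
          burstDurMs = c(120, 260) * subj$durScale,
          f0Hz = subj$f0,
          effectSize = es,
          f0Var = base$f0Var * subj$f0VarMul,
          jitter = base$jitter * subj$jitterMul,
          shimmer = base$shimmer * subj$shimmerMul,
          breathNoiseDb = base$breathNoiseDb + subj$noiseAdd,
          formantBwScale = max(1, base$formantBwScale * subj$bwMul),
          sampleRate = sampleRate, seed = clipSeed)
        clip <- synthesizeLaugh(spec)
        cid <- sprintf("%s_l%02d", sid, j)
        clip <- initialize(clip, subjectId = sid, classLabel = cls,
                           sex = sx, clipId = cid)
        clips[[k]] <- clip
        rows[[k]] <- data.frame(clip_id = cid, subject_id = sid,
                                class_label = cls, sex = sx, seed = clipSeed)
      }
    }
  }
  list(clips = clips, manifest = do.call(rbind, rows))
}
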