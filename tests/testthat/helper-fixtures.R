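# Shared fixtures, generated in code at test time.

# a clean sinusoid clip
sineClip <- function(freq = 1000, durSec = 1, rate = 16000, amp = 0.5) {
  t <- seq(0, durSec - 1 / rate, by = 1 / rate)
  AudioClip(amp * sin(2 * pi * freq * t), rate)
}

# deterministic pseudo-laugh for feature tests (cheap, no bursts logic)
noiseClip <- function(seed = 1, durSec = 0.5, rate = 16000) {
  withr::with_seed(seed, AudioClip(stats::rnorm(durSec * rate) * 0.2, rate))
}

# brute-force DFT: X(k) = sum_n x(n) exp(-2 pi i k n / N)
bruteDft <- function(x, nfft = length(x)) {
  x <- c(x, rep(0, nfft - length(x)))
  n <- 0:(nfft - 1)
  vapply(0:(nfft %/% 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * n / nfft)))^2
  }, numeric(1))
}

# brute-force log/DCT cepstrum (double loop)
bruteCepstra <- function(s, nCoeffs) {
  M <- length(s)
  vapply(seq_len(nCoeffs), function(n) {
    acc <- 0
    for (m in seq_len(M)) {
      acc <- acc + log10(s[m]) * cos(pi * n * (m - 0.5) / M)
    }
    acc
  }, numeric(1))
}

# Mann-Whitney concordance AUC with 1/2 tie credit
mannWhitneyAuc <- function(scores, labels) {
  pos <- scores[labels == "pd" | labels == 1]
  neg <- scores[!(labels == "pd" | labels == 1)]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# diagonal-MVN feature cohorts with a given mean separation delta spread
# over the first nInf components (unit variances); each record is its own
# CV group
mvnCohortPair <- function(nPerClass, delta, nFeatures = 156, nInf = 26,
                          seed = 1) {
  shift <- rep(0, nFeatures)
  shift[seq_len(nInf)] <- delta / sqrt(nInf)
  nm <- if (nFeatures == 156) featureLayout(FeatureSelection()) else
    paste("c", "mean", seq_len(nFeatures), sep = ".")
  mh <- CohortModel(stats::setNames(rep(0, nFeatures), nm),
                    rep(1, nFeatures), classLabel = "healthy", sex = "f")
  mp <- CohortModel(stats::setNames(shift, nm),
                    rep(1, nFeatures), classLabel = "pd", sex = "f")
  cbindFeatureSets(sampleCohort(mh, nPerClass, seed = seed),
                   sampleCohort(mp, nPerClass, seed = seed + 5000L))
}
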