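# Front-end: WAV loading, pre-emphasis, framing, power spectra.

test_that("loadClip conserves duration, passes 16 kHz audio through, and averages stereo", {
  tmp <- withr::local_tempdir()

  # 1 s at 44.1 kHz resampled to 16 kHz keeps its duration
  p44 <- file.path(tmp, "a44.wav")
  t44 <- seq(0, 1 - 1 / 44100, by = 1 / 44100)
  writeWavPcm(0.5 * sin(2 * pi * 440 * t44), p44, sampleRate = 44100)
  clip <- loadClip(p44, targetRate = 16000)
  expect_equal(length(samples(clip)), 16000)
  expect_equal(sampleRate(clip), 16000)

  # already at 16 kHz: no resampling path, samples identical after scaling
  p16 <- file.path(tmp, "a16.wav")
  x <- round(0.25 * sin(2 * pi * 300 * seq(0, 0.5, by = 1 / 16000)) * 32767) / 32767
  writeWavPcm(x, p16, sampleRate = 16000)
  clip16 <- loadClip(p16)
  expect_equal(samples(clip16), x, tolerance = 1 / 32767)

  # stereo with identical channels averages to either channel
  pst <- file.path(tmp, "stereo.wav")
  mono <- as.integer(round(0.3 * sin(2 * pi * 200 * seq(0, 0.5, by = 1 / 16000)) * 32767))
  con <- file(pst, "wb")
  interleaved <- as.integer(rbind(mono, mono))
  dataSize <- 2L * length(interleaved)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16000L, con, size = 4L, endian = "little")
  writeBin(64000L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4L, endian = "little")
  writeBin(interleaved, con, size = 2L, endian = "little")
  close(con)
  clipSt <- loadClip(pst)
  expect_equal(samples(clipSt), mono / 32768, tolerance = 1e-12)

  expect_error(loadClip(file.path(tmp, "missing.wav")), "not found")
})

test_that("WAV writer/reader round-trips within 16-bit quantisation", {
  tmp <- withr::local_tempfile(fileext = ".wav")
  x <- withr::with_seed(1, stats::runif(1000, -0.9, 0.9))
  writeWavPcm(x, tmp, sampleRate = 16000)
  back <- readWavPcm(tmp)
  expect_equal(back$sampleRate, 16000)
  expect_lt(max(abs(drop(back$samples) - x)), 1e-4)
})

test_that("pre-emphasis implements y(n) = x(n) - k x(n-1) with the documented frequency response", {
  expect_equal(preEmphasize(c(1, 1, 1), 0.97), c(1, 0.03, 0.03))

  # k -> 0 approaches the identity
  x <- withr::with_seed(2, stats::rnorm(64))
  expect_equal(preEmphasize(x, 1e-12), x, tolerance = 1e-9)

  expect_error(preEmphasize(x, 0), "strictly in")
  expect_error(preEmphasize(x, 1), "strictly in")

  # closed-form transfer function |1 - k e^{-jw}|: measure the empirical
  # gain on long sinusoids against direct evaluation on a frequency grid
  k <- 0.95
  rate <- 16000
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  for (f in c(0.0001, 1000, 3000, 7999.9)) {
    w <- 2 * pi * f / rate
    want <- Mod(1 - k * exp(-1i * w))
    x <- sin(2 * pi * f * t)
    y <- preEmphasize(x, k)
    got <- sqrt(mean(y[500:15500]^2) / mean(x[500:15500]^2))
    expect_lt(abs(got - want), 5e-3 * (1 + want))
  }
  # spot values: 1 - k at DC, 1 + k at Nyquist
  expect_equal(Mod(1 - k * exp(-1i * 0)), 1 - k)
  expect_equal(Mod(1 - k * exp(-1i * pi)), 1 + k)
})

test_that("framing yields floor((L - W)/H) + 1 Hanning-windowed frames", {
  # brute-force enumeration of sliding positions agrees with the formula
  cfg <- FramingConfig()
  clip <- sineClip(durSec = 1)         # L = 16000, W = 400, overlap 160
  frames <- frameAndWindow(clip, cfg)
  W <- 400L; H <- 240L
  nBrute <- 0L; pos <- 1L
  while (pos + W - 1L <= 16000L) { nBrute <- nBrute + 1L; pos <- pos + H }
  expect_equal(nrow(frames), nBrute)
  expect_equal(nrow(frames), 66L)
  expect_equal(ncol(frames), W)

  # L = W gives a single frame
  one <- AudioClip(rep(0.1, 400), 16000)
  expect_equal(nrow(frameAndWindow(one, cfg)), 1L)

  # an all-ones clip returns the Hanning window itself
  ones <- AudioClip(rep(1, 400), 16000)
  expect_equal(drop(frameAndWindow(ones, cfg)[1, ]), hanningWindow(400))

  expect_error(frameAndWindow(AudioClip(rep(0.1, 399), 16000), cfg),
               "too short")
})

test_that("power spectra match a brute-force DFT and conserve energy", {
  cfg <- FramingConfig()

  # zero frame -> zero power row
  z <- matrix(0, 1, 400)
  attr(z, "sampleRate") <- 16000
  expect_true(all(powerMatrix(powerSpectra(z, cfg)) == 0))

  # unit impulse (no windowing) -> flat unit power at every bin
  imp <- matrix(c(1, rep(0, 399)), 1)
  attr(imp, "sampleRate") <- 16000
  expect_equal(unname(drop(powerMatrix(powerSpectra(imp, cfg)))),
               rep(1, 257))

  # 1 kHz sinusoid peaks at bin 32 and matches the O(N^2) DFT
  clip <- sineClip(freq = 1000, amp = 1)
  frames <- frameAndWindow(clip, cfg, window = FALSE)
  spec <- powerSpectra(frames, cfg)
  row <- drop(powerMatrix(spec)[1, ])
  expect_equal(which.max(row) - 1L, 32L)
  brute <- bruteDft(frames[1, ], 512)
  expect_equal(row, brute, tolerance = 1e-9)
  expect_equal(binHz(spec), (0:256) * 16000 / 512)

  # Parseval: sum over all dftSize bins of |X|^2 equals N * frame energy;
  # reconstruct the two-sided sum from the one-sided half
  wf <- withr::with_seed(3, matrix(stats::rnorm(3 * 400), 3, 400))
  attr(wf, "sampleRate") <- 16000
  ps <- powerMatrix(powerSpectra(wf, cfg))
  for (i in 1:3) {
    twoSided <- sum(ps[i, ]) + sum(ps[i, 2:256])
    expect_equal(twoSided, 512 * sum(wf[i, ]^2), tolerance = 1e-6)
  }
})

test_that("delaying a clip by one hop shifts frames by one index and the pipeline is deterministic", {
  cfg <- FramingConfig()
  x <- withr::with_seed(4, stats::rnorm(4000) * 0.1)
  clip <- AudioClip(x, 16000)
  delayed <- AudioClip(c(rep(0, 240), x), 16000)
  f1 <- frameAndWindow(clip, cfg)
  f2 <- frameAndWindow(delayed, cfg)
  expect_equal(unname(f2[2:nrow(f2), ]), unname(f1[1:(nrow(f2) - 1L), ]))

  s1 <- clipSpectrogram(clip, cfg)
  s2 <- clipSpectrogram(clip, cfg)
  expect_identical(powerMatrix(s1), powerMatrix(s2))
})
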