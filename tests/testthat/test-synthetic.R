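# Synthetic data: MVN cohort models and the waveform laugh simulator.

test_that("cohort fitting recovers hand-computed moments", {
  nm <- featureLayout(FeatureSelection())
  v <- stats::setNames(rep(1, 156), nm)
  fsSame <- LaughFeatureSet(cbind(v, v),
    colData = data.frame(subject_id = c("a", "b"), class_label = "healthy",
                         sex = "f", clip_id = c("c1", "c2")))
  m <- fitCohortModel(fsSame, classLabel = "healthy", sex = "f")
  expect_equal(unname(cohortMean(m)), rep(1, 156))
  expect_equal(unname(cohortVariance(m)), rep(0, 156))

  # components {0, 2}: mean 1, variance 2 (n - 1 denominator)
  fs02 <- LaughFeatureSet(cbind(v * 0, v * 2),
    colData = data.frame(subject_id = c("a", "b"), class_label = "pd",
                         sex = "m", clip_id = c("c1", "c2")))
  m2 <- fitCohortModel(fs02, classLabel = "pd")
  expect_equal(unname(cohortMean(m2)), rep(1, 156))
  expect_equal(unname(cohortVariance(m2)), rep(2, 156))

  expect_error(fitCohortModel(fsSame, classLabel = "pd"), "at least 2")
})

test_that("cohort sampling is seeded, degenerate at zero variance, and concentrates correctly", {
  nm <- featureLayout(FeatureSelection())
  mu <- stats::setNames(seq(-2, 2, length.out = 156), nm)

  degen <- CohortModel(mu, rep(0, 156), classLabel = "healthy", sex = "f")
  s <- sampleCohort(degen, 5, seed = 1)
  a <- SummarizedExperiment::assay(s, "features")
  expect_true(all(a == mu))

  model <- CohortModel(mu, stats::setNames(seq(0.5, 2, length.out = 156), nm),
                       classLabel = "pd", sex = "m")
  # reproducible per seed
  s1 <- sampleCohort(model, 50, seed = 9)
  s2 <- sampleCohort(model, 50, seed = 9)
  expect_identical(SummarizedExperiment::assay(s1), SummarizedExperiment::assay(s2))

  # chi-square concentration: per-component sample variance of 10,000 draws
  # within 10% of the model variance, and means within 4 SD / sqrt(n)
  big <- t(SummarizedExperiment::assay(sampleCohort(model, 10000, seed = 4)))
  sv <- apply(big, 2, stats::var)
  expect_true(all(abs(sv - cohortVariance(model)) / cohortVariance(model) < 0.1))
  bound <- 4 * sqrt(cohortVariance(model)) / sqrt(10000)
  expect_true(all(abs(colMeans(big) - mu) < bound))

  # law-of-large-numbers loop-back: refit recovers the generator
  refit <- fitCohortModel(
    sampleCohort(model, 10000, seed = 21), classLabel = "pd")
  expect_equal(unname(cohortMean(refit)), unname(mu), tolerance = 0.1)
})

test_that("cohort models round-trip through their tabular format", {
  nm <- featureLayout(FeatureSelection())
  model <- CohortModel(stats::setNames(stats::rnorm(156), nm),
                       rep(1.5, 156), classLabel = "pd", sex = "f",
                       nSource = 30L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeCohortModel(model, tmp)
  back <- readCohortModel(tmp)
  expect_equal(cohortMean(back), cohortMean(model), tolerance = 1e-10)
  expect_equal(classLabel(back), "pd")
  expect_equal(back@nSource, 30L)
})

test_that("synthesized laughs are deterministic and hit the requested pitch", {
  spec <- laughSynthSpec(effectSize = 0, seed = 12)
  c1 <- synthesizeLaugh(spec)
  c2 <- synthesizeLaugh(spec)
  expect_identical(samples(c1), samples(c2))
  expect_equal(sampleRate(c1), 16000)
  expect_lte(max(abs(samples(c1))), 0.9 + 1e-12)

  # autocorrelation pitch oracle: pure train at 280 Hz, no jitter/excursion
  clean <- synthesizeLaugh(laughSynthSpec(f0Hz = 280, jitter = 0, f0Var = 0,
                                          effectSize = 0, seed = 5))
  p <- pitchStats(clean)
  expect_equal(unname(p["f0.mean"]), 280, tolerance = 0.02 * 280)

  expect_error(laughSynthSpec(effectSize = 2), "\\[0, 1\\]")
  expect_error(laughSynthSpec(nBursts = c(5, 2)), "range")
})

test_that("perturbation doses respond monotonically to the effect size", {
  # measured cycle-to-cycle F0 perturbation rises from healthy to PD-like
  jitterProxy <- function(effect, seed) {
    clip <- synthesizeLaugh(laughSynthSpec(f0Hz = 240, f0Var = 0,
                                           effectSize = effect, seed = seed))
    f0 <- trackF0(clip, frameMs = 30, hopMs = 10)
    mean(abs(diff(f0)) / f0[-length(f0)])
  }
  j0 <- mean(vapply(1:4, function(s) jitterProxy(0, s), numeric(1)))
  j1 <- mean(vapply(1:4, function(s) jitterProxy(1, s), numeric(1)))
  expect_gt(j1, j0)

  # noise floor (quietest-frame RMS relative to loudest) rises with effect
  noiseProxy <- function(effect, seed) {
    clip <- synthesizeLaugh(laughSynthSpec(effectSize = effect, seed = seed))
    fr <- frameAndWindow(clip, FramingConfig(), window = FALSE)
    e <- sqrt(rowMeans(fr^2))
    stats::quantile(e, 0.1) / stats::quantile(e, 0.95)
  }
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  floors <- vapply(grid, function(es)
    mean(vapply(1:4, function(s) noiseProxy(es, s), numeric(1))), numeric(1))
  expect_true(all(diff(floors) > -0.01))  # non-decreasing within jitter of the estimate
  expect_gt(floors[5], floors[1])
})

test_that("the simulated study is balanced, correlated within subject, and seeded", {
  st <- makeSyntheticStudy(3, 2, effectSize = 0.5, seed = 8)
  expect_length(st$clips, 3 * 2 * 4)
  man <- st$manifest
  expect_equal(as.integer(table(man$class_label)), c(12L, 12L))
  expect_equal(as.integer(table(man$sex)), c(12L, 12L))
  expect_equal(length(unique(man$subject_id)), 12L)
  expect_equal(as.integer(table(man$subject_id))[1], 2L)

  st2 <- makeSyntheticStudy(3, 2, effectSize = 0.5, seed = 8)
  expect_identical(samples(st$clips[[1]]), samples(st2$clips[[1]]))
  expect_identical(samples(st$clips[[24]]), samples(st2$clips[[24]]))

  # different seed, different audio
  st3 <- makeSyntheticStudy(3, 2, effectSize = 0.5, seed = 9)
  expect_false(identical(samples(st$clips[[1]]), samples(st3$clips[[1]])))
})

test_that("a null study produces null feature-wise t statistics", {
  st <- makeSyntheticStudy(8, 2, effectSize = 0, seed = 31)
  fs <- extractFeatureSet(st$clips)
  mat <- SummarizedExperiment::assay(fs, "features")
  cls <- SummarizedExperiment::colData(fs)$class_label
  tt <- apply(mat, 1, function(row) {
    stats::t.test(row[cls == "pd"], row[cls == "healthy"])$statistic
  })
  # with 156 correlated features and no class effect, |t| > 3 should be rare
  expect_lte(mean(abs(tt) > 3), 0.03)
})
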