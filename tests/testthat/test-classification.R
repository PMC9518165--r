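# Fold construction, metrics, and the cross-validated training loop.

test_that("grouped folds partition subjects and never split a group", {
  subj <- paste0("s", 1:20)
  plan <- makeFolds(subj, k = 10, seed = 2)
  fa <- foldAssignment(plan)
  expect_length(fa, 20L)
  expect_equal(as.integer(table(fa)), rep(2L, 10))

  # records duplicated across a subject stay in one fold
  records <- rep(subj, each = 7)
  folds <- fa[records]
  perSubject <- tapply(folds, records, function(f) length(unique(f)))
  expect_true(all(perSubject == 1L))

  expect_error(makeFolds(subj, k = 1), ">= 2")
  expect_error(makeFolds(paste0("s", 1:5), k = 10), "fewer distinct groups")
})

test_that("MCC matches hand-worked confusions and is label-swap symmetric", {
  # balanced 100 + 100 cohort at TPR 0.84 / TNR 0.82
  expect_equal(round(mccFromConfusion(84, 18, 82, 16), 2), 0.66)
  expect_equal(mccFromConfusion(50, 0, 50, 0), 1)
  expect_equal(mccFromConfusion(25, 25, 25, 25), 0)
  # degenerate marginal -> 0 by convention
  expect_equal(mccFromConfusion(0, 0, 10, 10), 0)
  # swapping the class labels (tp<->tn, fp<->fn) leaves MCC unchanged
  cases <- withr::with_seed(6, matrix(sample(0:50, 40, TRUE), ncol = 4))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, ]
    expect_equal(mccFromConfusion(x[1], x[2], x[3], x[4]),
                 mccFromConfusion(x[3], x[4], x[1], x[2]))
  }
  expect_error(mccFromConfusion(-1, 0, 1, 1), "non-negative")
})

test_that("ROC/AUC agrees with the Mann-Whitney concordance count", {
  labels <- rep(c("healthy", "pd"), each = 6)
  # scores equal to class indicators: perfect separation
  perfect <- rocAuc(as.numeric(labels == "pd"), labels)
  expect_equal(perfect$auc, 1)
  # all scores tied: a single diagonal segment, AUC 1/2
  flat <- rocAuc(rep(0.3, 12), labels)
  expect_equal(flat$auc, 0.5)
  expect_equal(nrow(flat$points), 2L)

  # randomized instances, with ties, against the concordance oracle
  for (s in 1:5) {
    scores <- withr::with_seed(s, sample(seq(0, 1, 0.05), 200, replace = TRUE))
    lab <- withr::with_seed(100 + s,
                            sample(c("healthy", "pd"), 200, replace = TRUE))
    got <- rocAuc(scores, lab)$auc
    expect_equal(got, mannWhitneyAuc(scores, lab), tolerance = 1e-12)
    # score negation reflects the curve: AUC -> 1 - AUC
    expect_equal(rocAuc(-scores, lab)$auc, 1 - got, tolerance = 1e-12)
  }
  expect_error(rocAuc(1:5, rep("pd", 5)), "both classes")
})

test_that("ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  scores <- withr::with_seed(9, stats::rnorm(150))
  lab <- withr::with_seed(10, sample(c("healthy", "pd"), 150, replace = TRUE))
  ours <- rocAuc(scores, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = scores,
                                        levels = c("healthy", "pd"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("all three families solve a perfectly separated problem", {
  n <- 40
  x <- withr::with_seed(11, rbind(matrix(stats::rnorm(n * 4), n, 4),
                                  matrix(stats::rnorm(n * 4) + 8, n, 4)))
  labels <- rep(c("healthy", "pd"), each = n)
  groups <- paste0("g", seq_len(2 * n))
  plan <- makeFolds(groups, k = 5, seed = 1)
  for (fam in c("rf", "knn", "svm")) {
    r <- trainEval(x, ClassifierSpec(fam, rfTrees = 50), plan,
                   labels = labels, groups = groups)
    expect_equal(arPercent(r), 100)
    expect_equal(mccValue(r), 1)
    expect_equal(aucValue(r), 1)
  }
})

test_that("permuted labels put every family at chance", {
  n <- 150
  x <- withr::with_seed(12, matrix(stats::rnorm(2 * n * 10), 2 * n, 10))
  labels <- withr::with_seed(13, sample(rep(c("healthy", "pd"), each = n)))
  groups <- paste0("g", seq_len(2 * n))
  plan <- makeFolds(groups, k = 5, seed = 2)
  se3 <- 3 * 100 * sqrt(0.25 / (2 * n))   # 3 binomial SEs in AR points
  for (fam in c("rf", "knn", "svm")) {
    r <- trainEval(x, ClassifierSpec(fam, rfTrees = 50), plan,
                   labels = labels, groups = groups)
    expect_lt(abs(arPercent(r) - 50), se3)
    expect_lt(abs(aucValue(r) - 0.5), 0.1)
  }
})

test_that("random-forest results agree in kind with an independent RF", {
  skip_if_not_installed("randomForest")
  fs <- mvnCohortPair(150, 2.5, seed = 3)
  cd <- SummarizedExperiment::colData(fs)
  plan <- makeFolds(cd$subject_id, k = 5, seed = 1)
  ours <- trainEval(fs, ClassifierSpec("rf"), plan)

  # independent oracle: randomForest under the same folds
  x <- t(SummarizedExperiment::assay(fs, "features"))
  y <- factor(cd$class_label, levels = c("healthy", "pd"))
  fa <- foldAssignment(plan)[cd$subject_id]
  pred <- character(nrow(x))
  for (f in 1:5) {
    te <- fa == f
    fit <- withr::with_seed(f, randomForest::randomForest(
      x[!te, ], y[!te], ntree = 100))
    pred[te] <- as.character(predict(fit, x[te, ]))
  }
  refAr <- 100 * mean(pred == cd$class_label)
  expect_lt(abs(arPercent(ours) - refAr), 7)
})

test_that("standardisation makes kNN and SVM invariant to global affine feature maps", {
  fs <- mvnCohortPair(80, 2, seed = 4)
  cd <- SummarizedExperiment::colData(fs)
  x <- t(SummarizedExperiment::assay(fs, "features"))
  plan <- makeFolds(cd$subject_id, k = 4, seed = 5)
  scaled <- sweep(sweep(x, 2, seq_len(ncol(x)) * 3, `*`), 2, 100, `+`)
  for (fam in c("knn", "svm")) {
    r1 <- trainEval(x, ClassifierSpec(fam), plan,
                    labels = cd$class_label, groups = cd$subject_id)
    r2 <- trainEval(scaled, ClassifierSpec(fam), plan,
                    labels = cd$class_label, groups = cd$subject_id)
    expect_equal(r1@predictions$predicted, r2@predictions$predicted)
    expect_equal(arPercent(r1), arPercent(r2))
  }
})

test_that("training-split degeneracies are reported", {
  x <- matrix(stats::rnorm(40), 20, 2)
  groups <- paste0("g", 1:20)
  plan <- makeFolds(groups, k = 4, seed = 1)
  expect_error(trainEval(x, ClassifierSpec("knn"), plan,
                         labels = rep("pd", 20), groups = groups),
               "single class")
  x[1, 1] <- NA
  expect_error(trainEval(x, ClassifierSpec("knn"), plan,
                         labels = rep(c("pd", "healthy"), 10), groups = groups),
               "non-finite")
})

test_that("the evaluation report is internally consistent", {
  fs <- mvnCohortPair(100, 2, seed = 6)
  plan <- makeFolds(SummarizedExperiment::colData(fs)$subject_id,
                    k = 5, seed = 2)
  r <- trainEval(fs, ClassifierSpec("knn", knnK = 3), plan)
  # per-class rate convention: TPR + FNR = 1, TNR + FPR = 1
  expect_equal(r@tpRate + r@fnRate, 1)
  expect_equal(r@tnRate + r@fpRate, 1)
  # AR from the pooled confusion matrix equals the definition
  cm <- r@confusion
  expect_equal(arPercent(r), 100 * sum(diag(cm)) / sum(cm))
  # AR consistent with the rates under the class balance
  expect_equal(arPercent(r), 100 * (r@tpRate + r@tnRate) / 2, tolerance = 1e-9)
  expect_gte(aucValue(r), 0)
  expect_lte(aucValue(r), 1)
})
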