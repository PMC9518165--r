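# Classifier families (RF / kNN / nu-SVC), grouped cross-validation, and
# the pooled evaluation metrics (AR, confusion rates, MCC, ROC/AUC).

POSITIVE_CLASS <- "pd"

#' Build a grouped cross-validation plan
#'
#' Shuffles the distinct grouping units (typically subjects) with `seed`
#' and deals them round-robin into `k` folds, so all records of one group
#' share a fold and no group straddles folds.
#'
#' @param groups vector of group labels, one per record (or just the
#'   distinct labels).
#' @param k number of folds (default 10); must be at least 2 and at most
#'   the number of distinct groups.
#' @param seed integer seed for the shuffle.
#' @return A [CVPlan-class].
#' @export
makeFolds <- function(groups, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2 (one fold leaves no training segment)")
  u <- unique(as.character(groups))
  if (length(u) < k) stop("fewer distinct groups (", length(u), ") than folds (", k, ")")
  shuffled <- withr::with_seed(as.integer(seed), sample(u))
  fold <- rep_len(seq_len(k), length(u))
  names(fold) <- shuffled
  new("CVPlan", kFolds = k, foldAssignment = fold[order(names(fold))])
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(tp tn - fp fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; defined as 0
#' when any marginal is empty (the correlation of a constant prediction).
#'
#' @param tp,fp,tn,fn confusion counts (non-negative).
#' @return MCC in \[-1, 1\].
#' @examples
#' mccFromConfusion(84, 18, 82, 16)  # 0.66 to two decimals
#' @export
mccFromConfusion <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique scores (tied scores form one threshold
#' step), returning the (FPR, TPR) staircase and its trapezoidal area. With
#' ties handled this way the AUC equals the Mann-Whitney concordance
#' statistic with the 1/2 tie correction.
#'
#' @param scores numeric scores, larger meaning more positive-like.
#' @param labels binary labels; the positive class is `"pd"` (or 1/TRUE).
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  pos <- .isPositive(labels)
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) stop("both classes must be present for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # cumulative counts at each distinct-score threshold
  keep <- which(c(diff(s) != 0, TRUE))
  tpr <- c(0, cumsum(p)[keep] / nP)
  fpr <- c(0, cumsum(!p)[keep] / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

.isPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == max(labels))
  as.character(labels) == POSITIVE_CLASS
}

# deterministic kNN: Euclidean distance, distance ties broken by smaller
# training-record index, even-k vote ties broken toward the positive (pd)
# class - favouring sensitivity, the clinically preferred error trade-off.
.knnPredict <- function(xtr, ytr, xte, k) {
  k <- min(k, nrow(xtr))
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), `+`) - 2 * xte %*% t(xtr)
  posTr <- .isPositive(ytr)
  t(apply(d2, 1L, function(row) {
    nb <- order(row, seq_along(row))[seq_len(k)]  # index breaks distance ties
    fracPos <- mean(posTr[nb])
    c(score = fracPos, pred = as.numeric(fracPos >= 0.5))
  }))
}

.standardize <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2L, stats::sd)
  sg[sg < 1e-12] <- 1
  list(tr = sweep(sweep(xtr, 2L, mu), 2L, sg, `/`),
       te = sweep(sweep(xte, 2L, mu), 2L, sg, `/`))
}

.svmKernelArgs <- function(kernel, nu) {
  base <- sub("^nu_", "", kernel)
  list(type = if (grepl("^nu_", kernel)) "nu-classification" else "C-classification",
       kernel = switch(base, linear = "linear", poly3 = "polynomial",
                       rbf = "radial"),
       degree = 3L, nu = nu)
}

# fit on one training fold, return score (P(pd)-like) and prediction for the
# validation fold
.fitScore <- function(xtr, ytr, xte, spec) {
  if (spec@standardize && spec@family %in% c("knn", "svm")) {
    z <- .standardize(xtr, xte)
    xtr <- z$tr; xte <- z$te
  }
  yf <- factor(ytr, levels = c("healthy", "pd"))
  if (spec@family == "rf") {
    dtr <- as.data.frame(xtr); dte <- as.data.frame(xte)
    names(dtr) <- names(dte) <- paste0("f", seq_len(ncol(xtr)))
    dtr$.y <- yf
    fit <- ranger::ranger(dependent.variable.name = ".y", data = dtr,
                          num.trees = spec@rfTrees, probability = TRUE,
                          num.threads = 1L, seed = spec@seed)
    pr <- stats::predict(fit, data = dte, num.threads = 1L)$predictions
    score <- pr[, "pd"]
    pred <- ifelse(score >= 0.5, "pd", "healthy")
  } else if (spec@family == "knn") {
    out <- .knnPredict(xtr, ytr, xte, spec@knnK)
    score <- out[, "score"]
    pred <- ifelse(out[, "pred"] == 1, "pd", "healthy")
  } else {
    ka <- .svmKernelArgs(spec@svmKernel, spec@svmNu)
    fit <- e1071::svm(xtr, yf, type = ka$type, kernel = ka$kernel,
                      degree = ka$degree, nu = ka$nu, scale = FALSE)
    pv <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- drop(attr(pv, "decision.values"))
    # orient the decision value toward the positive class
    if (grepl("healthy/pd", colnames(attr(pv, "decision.values"))[1L])) {
      dv <- -dv
    }
    score <- dv
    pred <- as.character(pv)
  }
  list(score = as.numeric(score), pred = pred)
}

#' Train and evaluate a classifier under grouped cross-validation
#'
#' For each fold: fit the classifier on the training groups (z-scoring
#' features by training-fold statistics for kNN and SVM), score the held-out
#' records with a continuous score (RF: tree-vote fraction for the PD class;
#' kNN: neighbour-class fraction; SVM: decision value), and pool all
#' out-of-fold predictions into one [EvalReport-class]. The positive class
#' is `"pd"` throughout.
#'
#' @param x a [LaughFeatureSet-class], or a numeric matrix with one row per
#'   record.
#' @param spec a [ClassifierSpec-class].
#' @param plan a [CVPlan-class] over the record groups.
#' @param labels,groups required when `x` is a matrix: class labels
#'   (`"healthy"`/`"pd"`) and grouping labels per record. Taken from
#'   `colData` (`class_label`, `subject_id`) for a feature set.
#' @return An [EvalReport-class].
#' @export
trainEval <- function(x, spec, plan, labels = NULL, groups = NULL) {
  if (is(x, "LaughFeatureSet")) {
    cd <- SummarizedExperiment::colData(x)
    labels <- labels %||% as.character(cd$class_label)
    groups <- groups %||% as.character(cd$subject_id)
    x <- t(SummarizedExperiment::assay(x, "features"))
  }
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features contain non-finite values")
  groups <- as.character(groups)
  fold <- foldAssignment(plan)[groups]
  if (anyNA(fold)) stop("some records belong to groups absent from the CV plan")

  n <- nrow(x)
  score <- numeric(n); pred <- character(n)
  perFold <- list()
  for (f in seq_len(plan@kFolds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(te) == 0L) next
    if (length(unique(labels[tr])) < 2L) {
      stop("training split for fold ", f, " contains a single class")
    }
    out <- .fitScore(x[tr, , drop = FALSE], labels[tr],
                     x[te, , drop = FALSE], spec)
    score[te] <- out$score
    pred[te] <- out$pred
    perFold[[f]] <- data.frame(fold = f, n = length(te),
                               accuracy = mean(out$pred == labels[te]))
  }
  .evalReport(truth = labels, pred = pred, score = score, fold = fold,
              perFold = do.call(rbind, perFold))
}

.evalReport <- function(truth, pred, score, fold, perFold) {
  posT <- .isPositive(truth)
  posP <- .isPositive(pred)
  tp <- sum(posT & posP); fn <- sum(posT & !posP)
  tn <- sum(!posT & !posP); fp <- sum(!posT & posP)
  confusion <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                      dimnames = list(truth = c("healthy", "pd"),
                                      predicted = c("healthy", "pd")))
  roc <- rocAuc(score, truth)
  new("EvalReport",
      arPercent = 100 * (tp + tn) / length(truth),
      confusion = confusion,
      tpRate = tp / max(1L, tp + fn), fnRate = fn / max(1L, tp + fn),
      tnRate = tn / max(1L, tn + fp), fpRate = fp / max(1L, tn + fp),
      sensitivity = tp / max(1L, tp + fn),
      specificity = tn / max(1L, tn + fp),
      mcc = mccFromConfusion(tp, fp, tn, fn),
      rocPoints = roc$points, auc = roc$auc,
      perFold = perFold %||% data.frame(),
      predictions = data.frame(truth = truth, predicted = pred,
                               score = score, fold = fold))
}

#' Pitch feature matrix for a set of clips
#'
#' @param clips list of [AudioClip-class] objects.
#' @param ... passed to [pitchStats()].
#' @return records x 7 matrix of per-clip pitch statistics, with the clip
#'   metadata in attributes `labels` and `groups`.
#' @export
pitchFeatureMatrix <- function(clips, ...) {
  rows <- lapply(clips, pitchStats, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(clips, clipId, "")
  attr(m, "labels") <- vapply(clips, classLabel, "")
  attr(m, "groups") <- vapply(clips, subjectId, "")
  m
}

#' Pitch-ablation experiment
#'
#' Runs the same cross-validated protocol with three input sets - pitch
#' statistics only, cepstral moments only, and both combined - to measure
#' how much of the class signal lives in pitch. In the reference finding,
#' pitch-only inputs classify at chance while cepstral inputs do not.
#'
#' @param cepstralFs a [LaughFeatureSet-class] of cepstral moment vectors.
#' @param pitchMat matrix from [pitchFeatureMatrix()], rows aligned with
#'   the columns of `cepstralFs`.
#' @param spec a [ClassifierSpec-class].
#' @param plan a [CVPlan-class].
#' @return list with `pitchOnly`, `cepstraOnly`, `combined`
#'   ([EvalReport-class] each) and `ar` (named vector of the three ARs).
#' @export
ablationPitch <- function(cepstralFs, pitchMat, spec, plan) {
  cd <- SummarizedExperiment::colData(cepstralFs)
  labels <- as.character(cd$class_label)
  groups <- as.character(cd$subject_id)
  cep <- t(SummarizedExperiment::assay(cepstralFs, "features"))
  if (nrow(pitchMat) != nrow(cep)) {
    stop("pitch matrix rows must align with the feature-set columns")
  }
  rP <- trainEval(pitchMat, spec, plan, labels = labels, groups = groups)
  rC <- trainEval(cep, spec, plan, labels = labels, groups = groups)
  rB <- trainEval(cbind(cep, pitchMat), spec, plan, labels = labels,
                  groups = groups)
  list(pitchOnly = rP, cepstraOnly = rC, combined = rB,
       ar = c(pitch_only = arPercent(rP), cepstra_only = arPercent(rC),
              combined = arPercent(rB)))
}
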