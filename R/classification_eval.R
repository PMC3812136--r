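#' Classification metrics from confusion counts
#'
#' Standard binary metrics: accuracy, sensitivity, specificity and the
#' Matthews correlation coefficient (Mcc), the balanced quality score used
#' when class sizes are very unequal:
#' \deqn{Mcc = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with Mcc defined as 0 when any factor in the denominator is zero.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return list of class `ClassificationMetrics`: `acc`, `sn`, `sp`, `mcc`,
#'   `counts`.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  if (tp + fn == 0) stop("sensitivity undefined: no positive samples")
  if (tn + fp == 0) stop("specificity undefined: no negative samples")
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(acc = (tp + tn) / total,
                 sn = tp / (tp + fn),
                 sp = tn / (tn + fp),
                 mcc = mcc,
                 counts = c(TP = tp, TN = tn, FP = fp, FN = fn)),
            class = "ClassificationMetrics")
}

#' ROC curve and area from decision scores
#'
#' Sweeps a threshold over the unique scores (predict positive when
#' score >= threshold); points are (1 - Sp, Sn) and the area is computed by
#' the trapezoid rule.
#'
#' @param scores numeric decision values, larger = more positive.
#' @param labels true class labels.
#' @param positive which label is the positive class.
#' @return list: `points` (data frame `fpr`, `tpr`, `threshold`), `auc`.
#' @export
roc_curve <- function(scores, labels, positive) {
  is_pos <- labels == positive
  if (all(is_pos) || !any(is_pos)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[is_pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!is_pos] >= t), numeric(1))
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]; thr <- thr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

build_feature_matrix <- function(dataset, feature_ids) {
  in_mrna <- feature_ids %in% rownames(dataset$mrna)
  in_mirna <- feature_ids %in% rownames(dataset$mirna)
  missing <- feature_ids[!in_mrna & !in_mirna]
  if (length(missing) > 0)
    warning("dropping unmeasured feature(s): ", paste(missing, collapse = ", "))
  keep <- feature_ids[in_mrna | in_mirna]
  if (length(keep) == 0) stop("no measured features")
  rows <- lapply(keep, feature_profile, dataset = dataset)
  X <- t(do.call(rbind, rows))  # samples x features
  colnames(X) <- keep
  rownames(X) <- colnames(dataset$mrna)
  X
}

#' Leave-one-out SVM classification of samples from an FFL feature set
#'
#' Evaluates how well the genes and miRNAs of a feed-forward loop set
#' separate the sample classes. For each sample, a soft-margin SVM is
#' trained on all remaining samples — features z-scored with the training
#' fold's statistics — and the held-out sample is predicted. Confusion
#' counts are accumulated over all folds and a ROC curve is built from the
#' pooled per-fold decision values.
#'
#' @param dataset labeled `ParallelDataset`.
#' @param feature_ids gene/miRNA ids to use as features (unmeasured ones
#'   are dropped with a warning).
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost soft-margin cost C (default 1).
#' @param positive positive class label; defaults to the lexicographically
#'   first class.
#' @param labels optional label vector overriding `dataset$labels`.
#' @return list of class `ClassificationReport`: `acc`, `sn`, `sp`, `mcc`,
#'   `counts`, `roc` (points + auc), `predictions`.
#' @export
loocv_svm <- function(dataset, feature_ids, kernel = "linear", cost = 1,
                      positive = NULL, labels = NULL) {
  if (is.null(labels)) labels <- dataset$labels
  if (is.null(labels)) stop("dataset has no class labels")
  labels <- labels[colnames(dataset$mrna)]
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly two classes required")
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples")
  if (is.null(positive)) positive <- classes[1]
  X <- build_feature_matrix(dataset, feature_ids)
  n <- nrow(X)
  y <- factor(labels, levels = classes)
  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- (X[i, ] - mu) / sdv
    fit <- e1071::svm(Xtr, y[tr], kernel = kernel, cost = cost, scale = FALSE)
    pr <- stats::predict(fit, rbind(Xte), decision.values = TRUE)
    pred[i] <- as.character(pr)
    dv <- drop(attr(pr, "decision.values"))
    # orient the decision value so larger = more like the positive class
    lab <- colnames(attr(pr, "decision.values"))[1]
    first <- strsplit(lab, "/", fixed = TRUE)[[1]][1]
    score[i] <- if (first == positive) dv else -dv
  }
  tp <- sum(pred == positive & labels == positive)
  tn <- sum(pred != positive & labels != positive)
  fp <- sum(pred == positive & labels != positive)
  fn <- sum(pred != positive & labels == positive)
  m <- metrics_from_counts(tp, tn, fp, fn)
  roc <- roc_curve(score, labels, positive)
  structure(list(acc = m$acc, sn = m$sn, sp = m$sp, mcc = m$mcc,
                 counts = m$counts, roc = roc,
                 predictions = data.frame(sample = rownames(X),
                                          truth = labels, predicted = pred,
                                          score = score,
                                          stringsAsFactors = FALSE),
                 positive = positive),
            class = "ClassificationReport")
}

#' Label-permutation baseline for the LOOCV SVM
#'
#' Repeats the full leave-one-out evaluation with the class labels randomly
#' permuted, `n_perm` times, and averages the metrics. The baseline shows
#' what the same feature set achieves when the labels carry no information.
#'
#' @inheritParams loocv_svm
#' @param n_perm number of label permutations (default 100).
#' @param seed optional RNG seed.
#' @return list: averaged `acc`, `sn`, `sp`, `mcc`, plus `per_perm` (data
#'   frame of per-permutation metrics).
#' @export
permutation_baseline <- function(dataset, feature_ids, n_perm = 100L,
                                 kernel = "linear", cost = 1,
                                 positive = NULL, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  labels <- dataset$labels[colnames(dataset$mrna)]
  per <- lapply(seq_len(n_perm), function(p) {
    perm <- stats::setNames(sample(labels), names(labels))
    r <- loocv_svm(dataset, feature_ids, kernel = kernel, cost = cost,
                   positive = positive, labels = perm)
    c(acc = r$acc, sn = r$sn, sp = r$sp, mcc = r$mcc)
  })
  per <- as.data.frame(do.call(rbind, per))
  list(acc = mean(per$acc), sn = mean(per$sn), sp = mean(per$sp),
       mcc = mean(per$mcc), n_perm = as.integer(n_perm), per_perm = per)
}
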