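# Classification metrics and training-set conditioning (z-scoring, SMOTE).

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; defined as 0
#' when any factor of the denominator is zero.
#'
#' @param tp,tn,fp,fn non-negative confusion-table counts.
#' @return value between -1 and 1.
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity. Requires both classes present in
#' the truth.
#'
#' @inheritParams mcc
#' @return value between 0 and 1.
#' @export
balanced_accuracy <- function(tp, tn, fp, fn) {
  assert_that((tp + fn) > 0 && (tn + fp) > 0,
              "balanced accuracy undefined when a class is absent")
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half: the normalized rank-sum statistic.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 vector, TRUE/1 = positive.
#' @return value between 0 and 1.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  assert_that(np > 0 && nn > 0, "AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Confusion-table metrics from predictions
#' @param pred,truth logical vectors (TRUE = positive class).
#' @return list with tp, tn, fp, fn, mcc, ba.
#' @export
confusion_metrics <- function(pred, truth) {
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       mcc = mcc(tp, tn, fp, fn),
       ba = if ((tp + fn) > 0 && (tn + fp) > 0) {
         balanced_accuracy(tp, tn, fp, fn)
       } else NA_real_)
}

#' Fit-and-apply z-score normalization
#'
#' Per-feature means and SDs are estimated on the training set only and
#' applied to both sets; features constant in training map to 0 everywhere.
#'
#' @param train_trials training feature matrix (trials x features).
#' @param other_trials optional matrix to transform with the training
#'   statistics (validation or test set).
#' @return list with `train`, `other` (or NULL), `center`, `scale`.
#' @export
zscore_fit_apply <- function(train_trials, other_trials = NULL) {
  assert_that(nrow(train_trials) > 0, "empty training set")
  mu <- colMeans(train_trials)
  sd_ <- apply(train_trials, 2, stats::sd)
  zero <- !is.finite(sd_) | sd_ == 0
  sd_[zero] <- 1
  tr <- sweep(sweep(train_trials, 2, mu), 2, sd_, "/")
  tr[, zero] <- 0
  ot <- NULL
  if (!is.null(other_trials)) {
    ot <- sweep(sweep(other_trials, 2, mu), 2, sd_, "/")
    ot[, zero] <- 0
  }
  list(train = tr, other = ot, center = mu, scale = sd_)
}

#' SMOTE: synthetic minority over-sampling
#'
#' Synthesizes minority-class samples `x + u * (x_nn - x)` with
#' `u ~ U(0, 1)` and `x_nn` one of the `k` nearest minority neighbors
#' (k capped at minority count - 1), until the class counts are equal.
#' Already-balanced input is returned unchanged.
#'
#' @param x feature matrix (trials x features).
#' @param y logical/0-1 class vector.
#' @param k number of nearest neighbors.
#' @param seed RNG seed.
#' @return list with `x`, `y` (balanced), and `synthetic` (logical marker).
#' @export
smote_balance <- function(x, y, k = 5, seed = NULL) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == n0) {
    return(list(x = x, y = y, synthetic = rep(FALSE, length(y))))
  }
  minority <- if (n1 < n0) y else !y
  n_min <- sum(minority); n_need <- abs(n1 - n0)
  assert_that(n_min >= 2, "SMOTE requires at least 2 minority samples")
  xm <- x[minority, , drop = FALSE]
  k <- min(k, n_min - 1)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  ord <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1) matrix(ord, ncol = 1) else t(ord)
  synth <- with_seed(seed, {
    base_idx <- rep_len(seq_len(n_min), n_need)
    nb_pick <- nn[cbind(base_idx, sample.int(k, n_need, replace = TRUE))]
    u <- stats::runif(n_need)
    xm[base_idx, , drop = FALSE] +
      u * (xm[nb_pick, , drop = FALSE] - xm[base_idx, , drop = FALSE])
  })
  list(
    x = rbind(x, synth),
    y = c(y, rep(n1 < n0, n_need)),
    synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_need))
  )
}
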