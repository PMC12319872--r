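# Classifier evaluation: within-participant five-fold CV,
# leave-one-participant-out with transfer learning, and label-shuffle
# permutation significance. No information leaks from test partitions:
# z-score statistics, SMOTE samples and early-stopping selection derive
# from training partitions only.

#' Feature matrix of a labeled-trial set
#'
#' Flattens each trial's electrodes x frequencies periodic matrix
#' column-major (electrode fastest), giving 864 features for the 32 x 27
#' grid.
#'
#' @param trials a `labeled_trials`.
#' @return trials x features numeric matrix.
#' @export
trial_matrix <- function(trials) {
  t(vapply(trials$matrices, function(m) as.vector(m$periodic),
           numeric(length(as.vector(trials$matrices[[1]]$periodic)))))
}

#' Binary dataset for one dimension
#'
#' Drops trials labeled `"discarded"` on the dimension; class 1 = upper end.
#'
#' @param trials a `labeled_trials`.
#' @param dimension one of [thought_dimensions()].
#' @return list with `x` (matrix), `y` (0/1), `participant` (character).
#' @export
dimension_dataset <- function(trials, dimension) {
  cls <- trials$labels[, dimension]
  keep <- cls != "discarded"
  x <- trial_matrix(trials)[keep, , drop = FALSE]
  list(x = x, y = as.integer(cls[keep] == "upper"),
       participant = trials$meta$participant[keep])
}

# fold metrics for one train/val/test split (shared by both CV modes)
.fit_eval <- function(xtr, ytr, xva, yva, xte, yte, config, smote_k, seed,
                      base_model = NULL) {
  z <- zscore_fit_apply(xtr, rbind(xva, xte))
  nva <- nrow(xva)
  xva_z <- z$other[seq_len(nva), , drop = FALSE]
  xte_z <- z$other[nva + seq_len(nrow(xte)), , drop = FALSE]
  bal <- smote_balance(z$train, ytr, k = smote_k,
                       seed = stage_seed(seed, "smote"))
  model <- base_model %||% build_scnn(config, seed = stage_seed(seed, "init"))
  model <- train_scnn(model, list(x = bal$x, y = as.integer(bal$y)),
                      list(x = xva_z, y = yva), config = config,
                      seed = stage_seed(seed, "train"))
  .eval_model(model, xte_z, yte)
}

.eval_model <- function(model, xte_z, yte) {
  P <- predict_scnn(model, xte_z)
  pred <- P[, 2] > 0.5
  cm <- confusion_metrics(pred, yte == 1)
  both <- length(unique(yte)) == 2
  c(mcc = cm$mcc,
    auc = if (both) auc(P[, 2], yte == 1) else NA_real_,
    ba = if (both) cm$ba else NA_real_)
}

#' Within-participant five-fold cross-validation
#'
#' For each participant with at least `min_class_trials` trials in each
#' class: per iteration, trials are randomly partitioned into 5 folds; each
#' fold in turn is the untouched test set, 10% of the remaining trials form
#' the validation set, z-scoring is fitted on the training portion, SMOTE
#' balances the training portion only, and a fresh 1D-SCNN is trained.
#' Fold metrics (MCC, AUC, BA) are averaged within participant, then across
#' participants; the summary reports mean and SD across iterations.
#'
#' @param trials a `labeled_trials` (task condition).
#' @param dimension dimension to decode.
#' @param config an `scnn_config`.
#' @param n_iterations number of repeats of the whole procedure.
#' @param seed root seed.
#' @param min_class_trials eligibility threshold per class (default 50).
#' @param n_folds number of folds.
#' @param val_frac fraction of the training data used for validation.
#' @param smote_k SMOTE neighbor count.
#' @param stratified if TRUE, folds are stratified by class.
#' @return a `performance_summary`: `per_iteration` (data.frame), `mean`,
#'   `sd`, `excluded` (participants below threshold), `n_participants`.
#' @export
within_participant_cv <- function(trials, dimension, config = scnn_config(),
                                  n_iterations = 25, seed = 1L,
                                  min_class_trials = 50, n_folds = 5,
                                  val_frac = 0.1, smote_k = 5,
                                  stratified = FALSE) {
  ds <- dimension_dataset(trials, dimension)
  parts <- unique(ds$participant)
  eligible <- character(0); excluded <- character(0)
  for (p in parts) {
    yp <- ds$y[ds$participant == p]
    if (min(sum(yp == 1), sum(yp == 0)) >= min_class_trials) {
      eligible <- c(eligible, p)
    } else excluded <- c(excluded, p)
  }
  assert_that(length(eligible) >= 1, "no participant meets the trial threshold")
  iter_rows <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    it_seed <- stage_seed(seed, paste0("iter", it))
    part_vals <- sapply(eligible, function(p) {
      xp <- ds$x[ds$participant == p, , drop = FALSE]
      yp <- ds$y[ds$participant == p]
      n <- nrow(xp)
      p_seed <- stage_seed(it_seed, p)
      folds <- with_seed(p_seed, {
        if (stratified) {
          f <- integer(n)
          for (cls in c(0, 1)) {
            idx <- which(yp == cls)
            f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
          }
          f
        } else sample(rep_len(seq_len(n_folds), n))
      })
      fold_vals <- vapply(seq_len(n_folds), function(k) {
        te <- which(folds == k)
        tr <- which(folds != k)
        va <- with_seed(stage_seed(p_seed, paste0("val", k)),
                        sample(tr, max(1, round(val_frac * length(tr)))))
        tr <- setdiff(tr, va)
        if (length(unique(yp[tr])) < 2) return(c(mcc = NA, auc = NA, ba = NA))
        .fit_eval(xp[tr, , drop = FALSE], yp[tr],
                  xp[va, , drop = FALSE], yp[va],
                  xp[te, , drop = FALSE], yp[te],
                  config, smote_k, stage_seed(p_seed, paste0("fold", k)))
      }, c(mcc = 0, auc = 0, ba = 0))
      rowMeans(fold_vals, na.rm = TRUE)
    })
    iter_rows[[it]] <- rowMeans(part_vals, na.rm = TRUE)
  }
  per_iter <- as.data.frame(do.call(rbind, iter_rows))
  .performance_summary(per_iter, dimension, "within_participant",
                       eligible, excluded)
}

.performance_summary <- function(per_iter, dimension, approach, eligible,
                                 excluded, extra = list()) {
  structure(c(list(
    per_iteration = per_iter,
    mean = colMeans(per_iter, na.rm = TRUE),
    sd = apply(per_iter, 2, stats::sd),
    dimension = dimension, approach = approach,
    participants = eligible, excluded = excluded
  ), extra), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("<performance_summary> %s (%s), %d iteration(s)\n",
              x$dimension, x$approach, nrow(x$per_iteration)))
  cat(sprintf("  MCC %.3f (%.3f)  AUC %.3f (%.3f)  BA %.3f (%.3f)\n",
              x$mean["mcc"], x$sd["mcc"], x$mean["auc"], x$sd["auc"],
              x$mean["ba"], x$sd["ba"]))
  if (length(x$excluded)) {
    cat("  excluded participants:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Leave-one-participant-out CV with transfer learning
#'
#' Per held-out participant: a base model is trained on all other
#' participants (90/10 train/validation split, SMOTE on the training part),
#' then adapted by re-training on a SMOTE-balanced random 25% of the test
#' participant's trials and evaluated on the remaining 75%. The 75% test
#' split never enters any training stage (an index audit is returned).
#' Unadapted metrics (base model on the same 75%) are reported alongside.
#'
#' @inheritParams within_participant_cv
#' @param adapt_frac fraction of the test participant's data used for
#'   adaptation (default 0.25).
#' @return a `performance_summary` (adapted) with extra fields
#'   `unadapted_mean`, `unadapted_per_iteration`, and `audit`.
#' @export
loso_transfer_cv <- function(trials, dimension, config = scnn_config(),
                             n_iterations = 25, seed = 1L,
                             min_class_trials = 50, adapt_frac = 0.25,
                             val_frac = 0.1, smote_k = 5) {
  ds <- dimension_dataset(trials, dimension)
  parts <- unique(ds$participant)
  eligible <- parts[vapply(parts, function(p) {
    yp <- ds$y[ds$participant == p]
    min(sum(yp == 1), sum(yp == 0)) >= min_class_trials
  }, logical(1))]
  excluded <- setdiff(parts, eligible)
  assert_that(length(eligible) >= 2, "LOSO requires at least 2 eligible participants")
  iter_ad <- vector("list", n_iterations)
  iter_un <- vector("list", n_iterations)
  audit <- list()
  for (it in seq_len(n_iterations)) {
    it_seed <- stage_seed(seed, paste0("loso", it))
    vals_ad <- NULL; vals_un <- NULL
    for (p in eligible) {
      p_seed <- stage_seed(it_seed, p)
      te_all <- which(ds$participant == p)
      tr_all <- which(ds$participant %in% setdiff(eligible, p))
      va <- with_seed(stage_seed(p_seed, "val"),
                      sample(tr_all, max(1, round(val_frac * length(tr_all)))))
      tr <- setdiff(tr_all, va)
      z <- zscore_fit_apply(ds$x[tr, , drop = FALSE],
                            ds$x[c(va, te_all), , drop = FALSE])
      xva <- z$other[seq_along(va), , drop = FALSE]
      xte_full <- z$other[length(va) + seq_along(te_all), , drop = FALSE]
      bal <- smote_balance(z$train, ds$y[tr], k = smote_k,
                           seed = stage_seed(p_seed, "smote"))
      base <- build_scnn(config, seed = stage_seed(p_seed, "init"))
      base <- train_scnn(base, list(x = bal$x, y = as.integer(bal$y)),
                         list(x = xva, y = ds$y[va]), config = config,
                         seed = stage_seed(p_seed, "train"))
      # split the held-out participant 25/75
      adapt_n <- max(2, round(adapt_frac * length(te_all)))
      ad_idx <- with_seed(stage_seed(p_seed, "adapt"),
                          sample(seq_along(te_all), adapt_n))
      te_idx <- setdiff(seq_along(te_all), ad_idx)
      x_ad <- xte_full[ad_idx, , drop = FALSE]
      y_ad <- ds$y[te_all][ad_idx]
      x_te <- xte_full[te_idx, , drop = FALSE]
      y_te <- ds$y[te_all][te_idx]
      vals_un <- cbind(vals_un, .eval_model(base, x_te, y_te))
      adapted <- base
      if (length(unique(y_ad)) == 2) {
        va2 <- with_seed(stage_seed(p_seed, "adval"),
                         sample(seq_along(y_ad),
                                max(1, round(val_frac * length(y_ad)))))
        tr2 <- setdiff(seq_along(y_ad), va2)
        if (length(unique(y_ad[tr2])) == 2 && min(table(y_ad[tr2])) >= 2) {
          bal2 <- smote_balance(x_ad[tr2, , drop = FALSE], y_ad[tr2],
                                k = smote_k,
                                seed = stage_seed(p_seed, "adsmote"))
          adapted <- train_scnn(base,
                                list(x = bal2$x, y = as.integer(bal2$y)),
                                list(x = x_ad[va2, , drop = FALSE],
                                     y = y_ad[va2]),
                                config = config,
                                seed = stage_seed(p_seed, "adtrain"))
        }
      }
      vals_ad <- cbind(vals_ad, .eval_model(adapted, x_te, y_te))
      if (it == 1) {
        audit[[p]] <- list(train_ids = tr, val_ids = va,
                           adapt_ids = te_all[ad_idx],
                           test_ids = te_all[te_idx])
      }
    }
    iter_ad[[it]] <- rowMeans(vals_ad, na.rm = TRUE)
    iter_un[[it]] <- rowMeans(vals_un, na.rm = TRUE)
  }
  per_ad <- as.data.frame(do.call(rbind, iter_ad))
  per_un <- as.data.frame(do.call(rbind, iter_un))
  .performance_summary(per_ad, dimension, "loso_transfer", eligible,
                       excluded,
                       extra = list(unadapted_per_iteration = per_un,
                                    unadapted_mean = colMeans(per_un,
                                                              na.rm = TRUE),
                                    audit = audit))
}

#' Shuffle one dimension's labels within participants
#'
#' @param trials a `labeled_trials`.
#' @param dimension dimension whose labels are permuted.
#' @param seed RNG seed.
#' @return the trials with the permuted label column.
#' @export
shuffle_dimension_labels <- function(trials, dimension, seed = NULL) {
  with_seed(seed, {
    for (p in unique(trials$meta$participant)) {
      idx <- which(trials$meta$participant == p)
      trials$labels[idx, dimension] <-
        trials$labels[sample(idx), dimension]
    }
    trials
  })
}

#' Label-shuffle permutation significance of decoding performance
#'
#' Runs the supplied pipeline `n_runs` times on the true labels and
#' `n_runs` times on labels shuffled within participant, then reports
#' `p_perm = (r + 1) / (n_runs + 1)` (rank of the observed mean among the
#' permuted means) and a two-sample Wilcoxon rank-sum p between the two
#' sets of run values.
#'
#' @param cv_runner function `(trials, dimension, seed) -> numeric` returning
#'   one performance value (e.g. mean MCC) per run.
#' @param trials a `labeled_trials`.
#' @param dimension dimension to decode.
#' @param n_runs runs per arm (default 25).
#' @param seed root seed.
#' @return list with `observed`, `permuted`, `p_perm`, `p_wilcoxon`.
#' @export
permutation_significance <- function(cv_runner, trials, dimension,
                                     n_runs = 25, seed = 1L) {
  observed <- vapply(seq_len(n_runs), function(i)
    cv_runner(trials, dimension, stage_seed(seed, paste0("obs", i))),
    numeric(1))
  permuted <- vapply(seq_len(n_runs), function(i) {
    sh <- shuffle_dimension_labels(trials, dimension,
                                   seed = stage_seed(seed, paste0("shuf", i)))
    cv_runner(sh, dimension, stage_seed(seed, paste0("perm", i)))
  }, numeric(1))
  r <- sum(permuted >= mean(observed))
  p_w <- suppressWarnings(
    stats::wilcox.test(observed, permuted, alternative = "greater")$p.value)
  list(observed = observed, permuted = permuted,
       p_perm = (r + 1) / (n_runs + 1), p_wilcoxon = p_w)
}
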