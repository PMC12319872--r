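# fast fake cv_runner used to test the permutation mechanics without
# CNN training: mean feature separation between classes
sep_runner <- function(trials, dimension, seed) {
  ds <- dimension_dataset(trials, dimension)
  lay <- make_layout()
  cells <- as.vector(outer(
    match(c("P7", "P3", "Pz", "P4", "P8", "PO3", "PO4", "O1", "Oz", "O2"),
          lay$labels), 5:14, function(e, b) e + 32 * (b - 1)))
  mean(ds$x[ds$y == 1, cells]) - mean(ds$x[ds$y == 0, cells])
}

mk_cv_trials <- function(n_per_class = 60, participants = "p1", shift = 0,
                         seed = 1) {
  set.seed(seed)
  # band-structured pattern: posterior electrodes, a contiguous bin block
  lay <- make_layout()
  cells <- as.vector(outer(
    match(c("P7", "P3", "Pz", "P4", "P8", "PO3", "PO4", "O1", "Oz", "O2"),
          lay$labels), 5:14, function(e, b) e + 32 * (b - 1)))
  parts <- list()
  for (p in participants) {
    n <- 2 * n_per_class
    y <- rep(c("lower", "upper"), n_per_class)
    x <- matrix(rnorm(n * 864), n)
    x[y == "upper", cells] <- x[y == "upper", cells] + shift
    labs <- matrix("discarded", n, 7,
                   dimnames = list(NULL, thought_dimensions()))
    labs[, "off_task"] <- y
    parts[[p]] <- mk_trials(x, labs, participant = p)
  }
  do.call(bind_trials, parts)
}

test_that("eligibility threshold excludes under-sampled participants", {
  tr_big <- mk_cv_trials(60, "p1")
  tr_small <- mk_cv_trials(49, "p2")
  both <- bind_trials(tr_big, tr_small)
  cfg <- scnn_config(max_epochs = 1, patience = 1)
  res <- within_participant_cv(both, "off_task", config = cfg,
                               n_iterations = 1, seed = 1,
                               min_class_trials = 50)
  expect_identical(res$participants, "p1")
  expect_identical(res$excluded, "p2")
  only_small <- mk_cv_trials(10, "p3")
  expect_error(within_participant_cv(only_small, "off_task", config = cfg,
                                     n_iterations = 1, seed = 1,
                                     min_class_trials = 50),
               "threshold")
})

test_that("within-participant CV decodes a strong planted pattern", {
  tr <- mk_cv_trials(55, c("p1", "p2"), shift = 1.5, seed = 2)
  cfg <- scnn_config(learning_rate = 3e-3, max_epochs = 12, patience = 12)
  res <- within_participant_cv(tr, "off_task", config = cfg,
                               n_iterations = 2, seed = 3,
                               min_class_trials = 50)
  expect_equal(nrow(res$per_iteration), 2)
  expect_gt(res$mean["mcc"], 0.5)
  expect_gt(res$mean["auc"], 0.75)
  expect_gt(res$mean["ba"], 0.7)
})

test_that("LOSO transfer isolates the held-out test split", {
  tr <- mk_cv_trials(55, c("p1", "p2", "p3"), shift = 1.2, seed = 4)
  cfg <- scnn_config(learning_rate = 3e-3, max_epochs = 6, patience = 6)
  res <- loso_transfer_cv(tr, "off_task", config = cfg, n_iterations = 1,
                          seed = 5, min_class_trials = 50)
  expect_setequal(res$participants, c("p1", "p2", "p3"))
  ds <- dimension_dataset(tr, "off_task")
  for (p in names(res$audit)) {
    a <- res$audit[[p]]
    # the 75% test split never enters any training stage
    expect_length(intersect(a$test_ids, a$adapt_ids), 0)
    expect_length(intersect(a$test_ids, a$train_ids), 0)
    expect_length(intersect(a$test_ids, a$val_ids), 0)
    # the base training pool contains no trials of the held-out participant
    expect_false(p %in% ds$participant[a$train_ids])
    expect_setequal(unique(ds$participant[c(a$adapt_ids, a$test_ids)]), p)
  }
  expect_true(all(is.finite(unlist(res$unadapted_mean))))
  expect_error(loso_transfer_cv(mk_cv_trials(55, "p1"), "off_task",
                                config = cfg, min_class_trials = 50),
               "at least 2")
})

test_that("label shuffling permutes within participants only", {
  tr <- mk_cv_trials(30, c("p1", "p2"), seed = 6)
  sh <- shuffle_dimension_labels(tr, "off_task", seed = 7)
  for (p in c("p1", "p2")) {
    idx <- tr$meta$participant == p
    expect_identical(sort(sh$labels[idx, "off_task"]),
                     sort(tr$labels[idx, "off_task"]))
  }
  expect_false(identical(sh$labels[, "off_task"], tr$labels[, "off_task"]))
  # other dimensions untouched
  expect_identical(sh$labels[, "self"], tr$labels[, "self"])
})

test_that("permutation significance ranks observed against shuffled runs", {
  tr <- mk_cv_trials(40, "p1", shift = 2, seed = 8)
  ps <- permutation_significance(sep_runner, tr, "off_task", n_runs = 10,
                                 seed = 9)
  expect_length(ps$observed, 10)
  expect_length(ps$permuted, 10)
  expect_equal(ps$p_perm, 1 / 11)  # strong effect outranks all permutations
  expect_lt(ps$p_wilcoxon, 0.01)
  # Wilcoxon side computed as the standard rank-sum test
  expect_equal(ps$p_wilcoxon,
               wilcox.test(ps$observed, ps$permuted,
                           alternative = "greater")$p.value)
})
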