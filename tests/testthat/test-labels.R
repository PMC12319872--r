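test_that("dichotomization follows the 1-3 / 4 / 5-7 rule", {
  expect_identical(dichotomize(2), "lower")
  expect_identical(dichotomize(4), "discarded")
  expect_identical(dichotomize(7), "upper")
  expect_identical(dichotomize(c(1, 3, 4, 5, NA)),
                   c("lower", "lower", "discarded", "upper", "discarded"))
  expect_error(dichotomize(0))
  expect_error(dichotomize(8))
  # counts equal direct tabulation on random report sets
  set.seed(7)
  r <- sample(1:7, 500, replace = TRUE)
  cls <- dichotomize(r)
  expect_identical(sum(cls == "lower"), sum(r <= 3))
  expect_identical(sum(cls == "upper"), sum(r >= 5))
  expect_identical(sum(cls == "discarded"), sum(r == 4))
})

fake_reports <- function(ratings_by_probe, probe_times) {
  df <- data.frame(participant = "p1", session = "s1", condition = "task",
                   probe_time_s = probe_times, scope = "momentary",
                   activity = "reading", stringsAsFactors = FALSE)
  cbind(df, as.data.frame(ratings_by_probe))
}

test_that("trials inherit their probe's labels per dimension", {
  set.seed(8)
  # epochs tiling 0..70 s, 3 probes at 24/48/70 with 12-s windows
  mats <- lapply(seq(0, 68, by = 2), function(t0)
    mk_spectral(matrix(rnorm(864), 32), t_start = t0))
  ratings <- matrix(5L, 3, 7, dimnames = list(NULL, thought_dimensions()))
  ratings[2, "off_task"] <- 4L
  ratings[3, "off_task"] <- 2L
  reps <- fake_reports(ratings, c(24, 48, 70))
  tr <- assemble_trials(mats, reps, window_s = 12)
  expect_length(tr$matrices, 18)  # 3 probes x 6 epochs
  tab <- table(tr$labels[, "off_task"])
  expect_equal(as.integer(tab[c("discarded", "lower", "upper")]),
               c(6L, 6L, 6L))
  # probe rated 4 is discarded on that dimension but usable on others
  expect_true(all(tr$labels[tr$meta$probe == 2, "self"] == "upper"))
  # empty report list -> empty output
  expect_length(assemble_trials(mats, reps[0, ], 12)$matrices, 0)
  # probe with no features is skipped with a warning
  expect_warning(assemble_trials(mats[1:3], reps, 12), "skipped")
})

test_that("session condition pairs exclude one-ended sessions", {
  set.seed(9)
  labs <- matrix("upper", 30, 7, dimnames = list(NULL, thought_dimensions()))
  tr <- mk_trials(matrix(rnorm(30 * 864), 30), labs)
  expect_null(session_condition_pairs(tr, "off_task"))
  labs2 <- labs
  labs2[1:10, "off_task"] <- "lower"
  tr2 <- mk_trials(matrix(rnorm(30 * 864), 30), labs2)
  pair <- session_condition_pairs(tr2, "off_task")
  expect_identical(pair$upper$n_trials, 20L)
  expect_identical(pair$lower$n_trials, 10L)
  # means equal direct oracle means of member trials
  x <- trial_matrix(tr2)
  expect_equal(as.vector(pair$lower$matrix$periodic),
               colMeans(x[1:10, ]), tolerance = 1e-12)
  expect_equal(as.vector(pair$upper$matrix$periodic),
               colMeans(x[11:30, ]), tolerance = 1e-12)
})

test_that("rest epochs inherit the retrospective label", {
  set.seed(10)
  mats <- lapply(seq(0, 298, by = 2), function(t0)
    mk_spectral(matrix(rnorm(864), 32), condition = "rest", t_start = t0))
  rep1 <- data.frame(participant = "p1", session = "s1", condition = "rest",
                     probe_time_s = 300, scope = "retrospective",
                     activity = NA)
  rep1 <- cbind(rep1, as.data.frame(matrix(6L, 1, 7,
    dimnames = list(NULL, thought_dimensions()))))
  tr <- label_rest(mats, rep1)
  expect_length(tr$matrices, 150)
  expect_true(all(tr$labels[, "sticky"] == "upper"))
  rep4 <- rep1
  rep4$self <- 4L
  expect_true(all(label_rest(mats, rep4)$labels[, "self"] == "discarded"))
  # blocks labeled independently: different reports stay distinct
  rep_lo <- rep1
  rep_lo[thought_dimensions()] <- 2L
  tr2 <- label_rest(mats[1:10], rep_lo)
  expect_true(all(tr2$labels[, "sticky"] == "lower"))
  expect_true(all(tr$labels[, "sticky"] == "upper"))
})

test_that("cohort-wide rest exclusions follow the any-participant rule", {
  mk_lab <- function(participant, cls) {
    df <- data.frame(participant = participant)
    for (d in thought_dimensions()) df[[d]] <- cls
    df
  }
  both <- rbind(mk_lab("p1", "upper"), mk_lab("p1", "lower"),
                mk_lab("p2", "upper"), mk_lab("p2", "lower"))
  expect_length(cohort_rest_exclusions(both), 0)
  # p2 never reports the upper end of freely_moving and internal
  skew <- both
  skew[skew$participant == "p2", c("freely_moving", "internal")] <- "lower"
  expect_setequal(cohort_rest_exclusions(skew),
                  c("freely_moving", "internal"))
  # all ratings <= 3 on one dimension for one participant excludes it
  one <- both
  one[one$participant == "p1", "sticky"] <- "lower"
  expect_identical(cohort_rest_exclusions(one), "sticky")
})

test_that("top correlated dimensions rank by |r| with Fisher-z pooling", {
  set.seed(11)
  n <- 40
  reps <- NULL
  for (s in c("s1", "s2")) {
    base <- sample(1:7, n, replace = TRUE)
    df <- data.frame(participant = rep("p1", n), session = s)
    df$off_task <- base
    df$freely_moving <- base                     # identical -> r = 1
    df$sticky <- sample(1:7, n, replace = TRUE)
    df$goal_directed <- sample(1:7, n, replace = TRUE)
    df$internal <- 8 - base                      # r = -1
    df$self <- sample(1:7, n, replace = TRUE)
    df$other <- rep(4L, n)                       # zero variance
    reps <- rbind(reps, df)
  }
  expect_warning(top <- top_correlated_dimensions(reps, "off_task"),
                 "zero-variance")
  expect_identical(top$p1[1:2], c("freely_moving", "internal"))
  expect_false("other" %in% top$p1)
  r <- attr(top$p1, "r")
  expect_identical(unname(r["other"]), 0)
  # independent ratings: pooled |r| stays small with many probes
  set.seed(12)
  big <- data.frame(participant = "p2", session = "s1")
  big <- cbind(big[rep(1, 2000), ],
               as.data.frame(matrix(sample(1:7, 2000 * 7, replace = TRUE),
                                    2000, dimnames = list(NULL,
                                      thought_dimensions()))))
  top2 <- top_correlated_dimensions(big, "off_task")
  expect_lt(max(abs(attr(top2$p2, "r"))), 0.1)
})
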