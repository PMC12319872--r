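test_that("latent trajectories match the target correlation", {
  cfg <- synth_config(correlation = diag(7))
  lat <- simulate_latents(cfg, 1e4, seed = 1)
  expect_equal(dim(lat), c(1e4, 7))
  cc <- cor(lat)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  expect_lt(max(abs(colMeans(lat))), 0.05)

  R <- diag(7)
  R[1, 2] <- R[2, 1] <- 0.9
  cfg2 <- synth_config(correlation = R)
  lat2 <- simulate_latents(cfg2, 1e4, seed = 2)
  expect_lt(abs(cor(lat2[, 1], lat2[, 2]) - 0.9), 0.03)

  expect_identical(simulate_latents(cfg, 50, seed = 7),
                   simulate_latents(cfg, 50, seed = 7))

  bad <- matrix(1, 7, 7)  # rank 1, not PD
  cfgb <- cfg
  cfgb$correlation <- bad
  expect_error(simulate_latents(cfgb, 10, seed = 1), "positive-definite")
})

test_that("latent-to-rating mapping centers, clips, and stays on scale", {
  expect_identical(latent_to_rating(0, 0), 4L)
  expect_identical(latent_to_rating(3, 0), 7L)
  expect_identical(latent_to_rating(-3, 0), 1L)
  set.seed(3)
  r <- latent_to_rating(rnorm(1e5), report_noise = 0.5, seed = 4)
  expect_true(all(r %in% 1:7))
  tab <- table(r)
  expect_identical(names(which.max(tab)), "4")
})

test_that("simulated sessions respect the probe schedule", {
  cfg <- synth_config(n_participants = 1, n_sessions = 1, seed = 5)
  ses <- simulate_session(cfg, seed = 6)
  pt <- ses$recording$probe_times
  expect_length(pt, 35)
  gaps <- diff(c(0, pt))
  expect_true(all(gaps >= 90 & gaps <= 150))
  expect_identical(ses$recording$condition, "task")
  expect_equal(nrow(ses$reports), 35)
  expect_true(all(unlist(ses$reports[thought_dimensions()]) %in% 1:7))
  # determinism
  ses2 <- simulate_session(cfg, seed = 6)
  expect_identical(ses$recording$data[, 1:100], ses2$recording$data[, 1:100])
})

test_that("planted effects raise oracle band power in upper-rated windows", {
  # direct periodogram oracle on the raw generated signal, bypassing the
  # package's spectral path
  cfg <- synth_config(n_participants = 1, n_sessions = 1, n_probes = 100,
                      probe_gap = c(20, 30), task_duration = 2600,
                      report_noise = 0,
                      effects = list(effect_spec(
                        "off_task", c("O1", "Oz", "O2", "PO3", "PO4"),
                        c(8, 9), gain = 0.5, sign = 1)),
                      seed = 8)
  ses <- simulate_session(cfg, seed = 9)
  fs <- cfg$sample_rate
  post <- match(c("O1", "Oz", "O2"), make_layout()$labels)
  pw <- vapply(seq_along(ses$recording$probe_times), function(i) {
    pt <- ses$recording$probe_times[i]
    idx <- (floor((pt - 12) * fs) + 1):floor(pt * fs)
    mean(vapply(post, function(ch)
      oracle_band_power(ses$recording$data[ch, idx], fs, c(8, 9)),
      numeric(1)))
  }, numeric(1))
  lat <- ses$ground_truth$latents[, "off_task"]
  expect_lt(t.test(log(pw[lat > 0]), log(pw[lat < 0]),
                   alternative = "greater")$p.value, 0.01)

  # zero gain: no difference in expectation
  cfg0 <- cfg
  cfg0$effects[[1]]$gain <- 0
  ses0 <- simulate_session(cfg0, seed = 9)
  pw0 <- vapply(seq_along(ses0$recording$probe_times), function(i) {
    pt <- ses0$recording$probe_times[i]
    idx <- (floor((pt - 12) * fs) + 1):floor(pt * fs)
    mean(vapply(post, function(ch)
      oracle_band_power(ses0$recording$data[ch, idx], fs, c(8, 9)),
      numeric(1)))
  }, numeric(1))
  lat0 <- ses0$ground_truth$latents[, "off_task"]
  expect_gt(t.test(log(pw0[lat0 > 0]), log(pw0[lat0 < 0]))$p.value, 0.05)
})

test_that("background spectrum recovers the configured 1/f exponent", {
  cfg <- synth_config(n_participants = 1, n_sessions = 1, n_probes = 5,
                      probe_gap = c(20, 30), task_duration = 150,
                      oscillators = list(), effects = list(),
                      aperiodic = list(offset = c(1, 1),
                                       exponent = c(1.2, 1.2)),
                      seed = 10)
  ses <- simulate_session(cfg, seed = 11)
  epochs <- segment_epochs(ses$recording)
  ps <- Reduce(`+`, lapply(epochs, function(e) welch_psd(e)$power)) /
    length(epochs)
  fit <- lm(log10(colMeans(ps)) ~ log10(frequency_grid()))
  expect_lt(abs(-coef(fit)[2] - 1.2), 0.1)
})

test_that("rest blocks are 5-minute retrospective recordings", {
  cfg <- synth_config(n_participants = 1, n_sessions = 1, seed = 12)
  rb <- simulate_rest(cfg, seed = 13)
  expect_equal(ncol(rb$recording$data) / cfg$sample_rate, 300)
  expect_identical(rb$recording$condition, "rest")
  expect_identical(rb$report$scope, "retrospective")
  expect_true(is.na(rb$report$activity))
  expect_true(is.na(rb$report$off_task))
  rb2 <- simulate_rest(cfg, seed = 13)
  expect_identical(rb$recording$data[, 1:50], rb2$recording$data[, 1:50])
})

test_that("cohort bookkeeping: counts, shared aperiodic draws, determinism", {
  cfg <- synth_config(n_participants = 7, n_sessions = 7, n_probes = 2,
                      probe_gap = c(16, 20), task_duration = 60,
                      rest_duration = 10, seed = 14)
  coh <- simulate_cohort(cfg)
  expect_length(coh$task, 49)
  expect_length(coh$rest, 98)
  # per-participant aperiodic parameters reused across sessions
  expect_identical(coh$task[["p01_s01"]]$ground_truth$aperiodic,
                   coh$task[["p01_s07"]]$ground_truth$aperiodic)
  cfg2 <- synth_config(n_participants = 2, n_sessions = 1, n_probes = 2,
                       probe_gap = c(16, 20), task_duration = 60,
                       rest_duration = 10, seed = 15)
  coh2 <- simulate_cohort(cfg2)
  expect_length(coh2$task, 2)
  expect_length(coh2$rest, 4)
  # same seed, byte-identical exported files
  f1 <- tempfile(fileext = ".edf"); f2 <- tempfile(fileext = ".edf")
  write_edf(simulate_cohort(cfg2)$task[[1]]$recording, f1)
  write_edf(simulate_cohort(cfg2)$task[[1]]$recording, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
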