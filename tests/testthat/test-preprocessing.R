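make_rec <- function(x, fs = 256) {
  data <- matrix(rep(x, each = 32), 32, byrow = FALSE)
  new_recording(data, fs, make_layout())
}

test_that("band-pass keeps in-band content and removes drift, zero phase", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  rec <- make_rec(sin(2 * pi * 10 * t))
  out <- bandpass_filter(rec)
  # PSD oracle: in-band variance preserved within 5%
  mid <- (5 * fs):(15 * fs)
  expect_lt(abs(sd(out$data[1, mid]) / sd(rec$data[1, mid]) - 1), 0.05)

  drift <- make_rec(sin(2 * pi * 0.1 * t))
  outd <- bandpass_filter(drift)
  atten_db <- 20 * log10(sd(outd$data[1, mid]) / sd(drift$data[1, mid]))
  expect_lt(atten_db, -20)

  # zero-phase: filtering a time-reversed signal and reversing equals
  # filtering
  set.seed(1)
  recr <- make_rec(rnorm(20 * fs))
  fwd <- bandpass_filter(recr)$data[1, ]
  rev_rec <- recr
  rev_rec$data <- rev_rec$data[, ncol(rev_rec$data):1]
  bwd <- rev(bandpass_filter(rev_rec)$data[1, ])
  # identical away from the boundary transients
  expect_lt(max(abs(fwd[mid] - bwd[mid])), 1e-6 * sd(fwd[mid]))

  expect_error(bandpass_filter(recr, 1, 130), "Nyquist")
})

test_that("notch removes line noise and leaves neighbors intact", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  mid <- (5 * fs):(15 * fs)
  line <- make_rec(sin(2 * pi * 60 * t))
  out <- notch_filter(line, 60)
  expect_lt(20 * log10(sd(out$data[1, mid]) / sd(line$data[1, mid])), -40)

  alpha <- make_rec(sin(2 * pi * 10 * t))
  outa <- notch_filter(alpha, 60)
  expect_lt(abs(sd(outa$data[1, mid]) / sd(alpha$data[1, mid]) - 1), 0.05)

  same <- notch_filter(alpha, numeric(0))
  expect_identical(same$data, alpha$data)
  expect_error(notch_filter(alpha, 128), "Nyquist")
})

test_that("epoch segmentation tiles the recording with reflected context", {
  fs <- 256
  set.seed(2)
  rec <- new_recording(matrix(rnorm(32 * 300 * fs), 32), fs, make_layout(),
                       condition = "rest")
  eps <- segment_epochs(rec)
  expect_length(eps, 150)
  starts <- vapply(eps, `[[`, numeric(1), "t_start")
  expect_identical(starts, seq(0, 298, by = 2))
  expect_true(all(vapply(eps, function(e)
    length(e$core_idx) == 2 * fs, logical(1))))
  # leading context of the first epoch is the time-reflection of its own
  # first second
  e1 <- eps[[1]]
  ctx <- e1$data[, 1:fs]
  core_first_s <- e1$data[, fs + (1:fs)]
  expect_identical(ctx, core_first_s[, fs:1])
  # short recording -> no epochs
  expect_length(segment_epochs(new_recording(matrix(0, 32, 100), fs,
                                             make_layout())), 0)
})

test_that("pre-probe windows select exactly the covered epochs", {
  fs <- 64
  rec <- new_recording(matrix(0, 32, 200 * fs), fs, make_layout())
  eps <- segment_epochs(rec)
  w <- preprobe_window(eps, 120, 12)
  expect_length(w, 6)
  st <- vapply(w, `[[`, numeric(1), "t_start")
  expect_true(all(st >= 108 & st + 2 <= 120))
  expect_length(preprobe_window(eps, 7, 12), 3)
  # probes >= 90 s apart never share an epoch (window <= 16 s)
  w1 <- preprobe_window(eps, 100, 16)
  w2 <- preprobe_window(eps, 190, 16)
  expect_length(intersect(vapply(w1, `[[`, numeric(1), "t_start"),
                          vapply(w2, `[[`, numeric(1), "t_start")), 0)
  expect_error(preprobe_window(eps, 120, 10))
})

test_that("common average reference zeroes the channel mean", {
  set.seed(3)
  ep <- mk_epoch(matrix(rnorm(32 * 1024), 32))
  out <- common_average_reference(ep)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  # idempotent
  out2 <- common_average_reference(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  # invariant to a common offset
  shifted <- ep
  shifted$data <- ep$data + 5
  expect_equal(common_average_reference(shifted)$data, out$data,
               tolerance = 1e-12)
  one <- ep
  one$data <- one$data[1, , drop = FALSE]
  expect_error(common_average_reference(one), "2 channels")
})
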