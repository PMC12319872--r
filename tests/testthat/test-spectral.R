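test_that("welch PSD matches the brute-force DFT oracle", {
  set.seed(4)
  x <- matrix(rnorm(32 * 1024), 32)  # 2-s core + 1-s context each side
  ep <- mk_epoch(x)
  got <- welch_psd(ep)
  expect_equal(dim(got$power), c(32, 27))
  want <- oracle_welch(x[, ep$core_idx])
  expect_lt(max(abs(got$power - want) / want), 1e-6)
})

test_that("welch PSD peaks at the frequency of a planted sinusoid", {
  fs <- 256
  t <- (0:(4 * fs - 1)) / fs
  x <- matrix(rep(sin(2 * pi * 10 * t), each = 32), 32, byrow = FALSE)
  ps <- welch_psd(mk_epoch(x))
  expect_true(all(apply(ps$power, 1, which.max) ==
                    which(frequency_grid() == 10)))
})

test_that("welch estimator is flat for white noise", {
  set.seed(5)
  fs <- 256
  acc <- matrix(0, 32, 27)
  n_ep <- 400  # 400 epochs x 32 channels = 12800 spectra
  for (i in seq_len(n_ep)) {
    acc <- acc + welch_psd(mk_epoch(matrix(rnorm(32 * 1024), 32)))$power
  }
  m <- colMeans(acc / n_ep)
  expect_lt((max(m) - min(m)) / mean(m), 0.05)
  # white noise with unit variance has one-sided density 2/fs
  expect_lt(abs(mean(m) - 2 / fs) / (2 / fs), 0.05)
})

test_that("aperiodic fit recovers exact power laws", {
  pl <- function(offset, expo) mk_spectral(matrix(0, 32, 27))
  rs <- structure(list(power = matrix(rep(10^2 * frequency_grid()^-1.5,
                                          each = 32), 32),
                       freqs = frequency_grid()), class = "raw_spectrum")
  fit <- fit_aperiodic(rs)
  expect_lt(max(abs(fit$offset - 2)), 1e-6)
  expect_lt(max(abs(fit$exponent - 1.5)), 1e-6)
  flat <- rs
  flat$power[] <- 5
  fitf <- fit_aperiodic(flat)
  expect_lt(max(abs(fitf$exponent)), 1e-9)
  bad <- rs
  bad$power[1, 1] <- 0
  expect_error(fit_aperiodic(bad), "positive")
})

test_that("aperiodic fit ignores an oscillatory peak; grid-search oracle agrees", {
  f <- frequency_grid()
  peak <- 0.5 * exp(-(f - 10)^2 / (2 * 1.5^2))
  ly <- 1.2 - 1.0 * log10(f) + peak
  rs <- structure(list(power = matrix(rep(10^ly, each = 32), 32),
                       freqs = f), class = "raw_spectrum")
  fit <- fit_aperiodic(rs)
  expect_lt(abs(fit$exponent[1] - 1.0), 0.1)
  # independent oracle: grid search over (offset, exponent) minimizing a
  # robust one-sided loss that penalizes the line exceeding the spectrum
  grid <- expand.grid(off = seq(0.8, 1.6, by = 0.01),
                      ex = seq(0.6, 1.4, by = 0.01))
  loss <- vapply(seq_len(nrow(grid)), function(i) {
    r <- ly - (grid$off[i] - grid$ex[i] * log10(f))
    sum(ifelse(r < 0, 4 * r^2, pmin(r, 0.25)^2))  # peaks barely penalized
  }, numeric(1))
  best <- grid[which.min(loss), ]
  expect_lt(abs(fit$exponent[1] - best$ex), 0.1)
})

test_that("periodic component is the log10 residual and adds back exactly", {
  f <- frequency_grid()
  # peakless power law -> residuals ~ 0
  rs <- structure(list(power = matrix(rep(10^(1 - 0.8 * log10(f)),
                                          each = 32), 32),
                       freqs = f), class = "raw_spectrum")
  fit <- fit_aperiodic(rs)
  pc <- periodic_component(rs, fit)
  expect_lt(max(abs(pc$periodic)), 1e-6)
  # planted peak -> residual maximum at its bin
  ly <- 1 - 0.8 * log10(f) + 0.5 * exp(-(f - 10)^2 / 2)
  rsp <- rs
  rsp$power <- matrix(rep(10^ly, each = 32), 32)
  fitp <- fit_aperiodic(rsp)
  pcp <- periodic_component(rsp, fitp)
  expect_true(all(apply(pcp$periodic, 1, which.max) == which(f == 10)))
  # algebraic identity: periodic + fitted line = log10 power
  ap <- outer(fitp$offset, rep(1, 27)) - outer(fitp$exponent, log10(f))
  expect_equal(unname(pcp$periodic + ap), unname(log10(rsp$power)),
               tolerance = 1e-12)
  # grid mismatch rejected
  fit_bad <- fitp
  fit_bad$freqs <- 5:31
  expect_error(periodic_component(rsp, fit_bad), "grid")
})

test_that("band table matches the canonical definitions and tiles 4-30 Hz", {
  expect_equal(band_range("high alpha"), c(10, 13))
  expect_equal(band_range("low theta"), c(4, 5))
  expect_error(band_range("gamma"), "unknown")
  bands <- band_range()
  bins <- unlist(lapply(bands, function(b) b[1]:b[2]))
  expect_equal(sort(unname(bins)), 4:30, ignore_attr = TRUE)
  expect_false(any(duplicated(bins)))
})

test_that("session mean equals the element-wise oracle mean", {
  set.seed(6)
  m <- rand_spectral()
  expect_equal(session_mean_matrix(list(m))$periodic, m$periodic)
  neg <- m
  neg$periodic <- -m$periodic
  expect_equal(max(abs(session_mean_matrix(list(m, neg))$periodic)), 0)
  ms <- lapply(1:100, function(i) rand_spectral())
  got <- session_mean_matrix(ms)$periodic
  want <- Reduce(`+`, lapply(ms, `[[`, "periodic")) / 100
  expect_lt(max(abs(got - want)), 1e-12)
  expect_error(session_mean_matrix(list()), "empty")
})
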