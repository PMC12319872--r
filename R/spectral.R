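# Spectral quantification: Welch PSD on the 4-30 Hz grid, aperiodic (1/f)
# fit-and-subtract, canonical band table, session-level averaging.

#' The 4-30 Hz analysis grid
#'
#' @return integer vector 4..30 (27 one-Hz bins).
#' @export
frequency_grid <- function() 4:30

#' Canonical frequency bands
#'
#' Six bands tiling 4-30 Hz: low theta (4-5), high theta (6-7), low alpha
#' (8-9), high alpha (10-13), low beta (14-20), high beta (21-30).
#'
#' @param name band name; if missing, the full table is returned.
#' @return `c(low_hz, high_hz)` for one band, or a named list of all six.
#' @export
band_range <- function(name) {
  bands <- list(
    "low theta"  = c(4, 5),
    "high theta" = c(6, 7),
    "low alpha"  = c(8, 9),
    "high alpha" = c(10, 13),
    "low beta"   = c(14, 20),
    "high beta"  = c(21, 30)
  )
  if (missing(name)) return(bands)
  key <- gsub("_", " ", tolower(name))
  assert_that(key %in% names(bands),
              sprintf("unknown band '%s'", name))
  bands[[key]]
}

#' Welch power spectral density of one epoch
#'
#' Averages Hamming-windowed periodograms over 1-s segments stepped by
#' 0.5 s across the 2-s epoch core (3 segments), and samples the result on
#' the 4-30 Hz 1-Hz grid. One-sided density in microvolts^2/Hz.
#'
#' @param epoch an `eeg_epoch` whose core is 2 s long.
#' @param seg_s segment length in seconds (default 1; gives the 1-Hz grid).
#' @param step_s hop between segment starts in seconds (default 0.5).
#' @return object of class `raw_spectrum`: `power` (electrodes x 27 matrix),
#'   `freqs`, plus epoch provenance.
#' @export
welch_psd <- function(epoch, seg_s = 1, step_s = 0.5) {
  fs <- epoch$sample_rate
  x <- epoch$data[, epoch$core_idx, drop = FALSE]
  n <- ncol(x)
  nseg <- round(seg_s * fs)
  step <- round(step_s * fs)
  assert_that(n >= nseg, "epoch core shorter than one Welch segment")
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  scale <- 2 / (fs * sum(w^2))  # one-sided density normalization
  freqs <- frequency_grid()
  bin <- freqs * seg_s + 1      # FFT bin index (1-based), resolution 1/seg_s
  acc <- matrix(0, nrow(x), length(freqs))
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1), drop = FALSE] *
      matrix(w, nrow(x), nseg, byrow = TRUE)
    ft <- t(stats::mvfft(t(seg)))
    acc <- acc + Mod(ft[, bin, drop = FALSE])^2 * scale
  }
  power <- acc / length(starts)
  dimnames(power) <- list(rownames(epoch$data), paste0(freqs, "Hz"))
  structure(list(power = power, freqs = freqs,
                 participant_id = epoch$participant_id,
                 session_id = epoch$session_id,
                 condition = epoch$condition,
                 t_start = epoch$t_start),
            class = "raw_spectrum")
}

# one robust line fit: OLS, drop points > 1 residual-SD ABOVE the line
# (spectral peaks), refit; `iter` extra refits.
.robust_logline <- function(lx, ly, iter = 2) {
  keep <- rep(TRUE, length(lx))
  fit <- NULL
  ols <- function(x, y) {
    xb <- mean(x); yb <- mean(y)
    b <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    c(yb - b * xb, b)
  }
  for (i in 0:iter) {
    cf <- ols(lx[keep], ly[keep])
    if (i == iter) { fit <- cf; break }
    resid <- ly[keep] - (cf[1] + cf[2] * lx[keep])
    s <- stats::sd(resid)
    if (!is.finite(s) || s == 0) { fit <- cf; break }
    drop_now <- resid > s
    if (!any(drop_now)) { fit <- cf; break }
    idx <- which(keep)
    keep[idx[drop_now]] <- FALSE
    if (sum(keep) < 3) { fit <- cf; break }
    fit <- cf
  }
  fit
}

#' Fit the aperiodic (1/f) component of a spectrum
#'
#' Per electrode, fits log10(power) = offset - exponent * log10(freq) by a
#' robust line: ordinary least squares, then excluding points more than one
#' residual-SD above the line (candidate oscillatory peaks) and refitting,
#' twice. Only this line is used downstream; Gaussian peak parameters are
#' not modeled.
#'
#' @param raw_spectrum a `raw_spectrum` with strictly positive power.
#' @return object of class `aperiodic_fit`: numeric vectors `offset` and
#'   `exponent`, one entry per electrode.
#' @export
fit_aperiodic <- function(raw_spectrum) {
  p <- raw_spectrum$power
  assert_that(all(p > 0), "power must be positive for the log-log fit")
  lx <- log10(raw_spectrum$freqs)
  fits <- apply(log10(p), 1, function(ly) .robust_logline(lx, ly))
  structure(list(offset = fits[1, ], exponent = -fits[2, ],
                 freqs = raw_spectrum$freqs),
            class = "aperiodic_fit")
}

#' Periodic (oscillatory) component of a spectrum
#'
#' Subtracts the fitted aperiodic line from the log10 spectrum:
#' `periodic = log10(power) - (offset - exponent * log10(freq))`. The result
#' is the electrode x frequency matrix of log10-power residuals used by all
#' downstream statistics (864 features per epoch for the 32 x 27 grid).
#'
#' @param raw_spectrum a `raw_spectrum`.
#' @param fit the `aperiodic_fit` obtained from the same spectrum.
#' @return object of class `spectral_matrix` with `periodic`
#'   (electrodes x 27), `freqs`, and provenance fields.
#' @export
periodic_component <- function(raw_spectrum, fit) {
  assert_that(identical(raw_spectrum$freqs, fit$freqs),
              "frequency grid mismatch between spectrum and fit")
  lf <- log10(raw_spectrum$freqs)
  ap <- outer(fit$offset, rep(1, length(lf))) -
    outer(fit$exponent, lf)
  periodic <- log10(raw_spectrum$power) - ap
  dimnames(periodic) <- dimnames(raw_spectrum$power)
  structure(list(periodic = periodic, freqs = raw_spectrum$freqs,
                 participant_id = raw_spectrum$participant_id,
                 session_id = raw_spectrum$session_id,
                 condition = raw_spectrum$condition,
                 t_start = raw_spectrum$t_start),
            class = "spectral_matrix")
}

#' Periodic spectral matrix of one epoch
#'
#' Convenience wrapper: Welch PSD, aperiodic fit, subtraction.
#' @inheritParams welch_psd
#' @return a `spectral_matrix`.
#' @export
epoch_spectral_matrix <- function(epoch) {
  rs <- welch_psd(epoch)
  periodic_component(rs, fit_aperiodic(rs))
}

#' Element-wise mean of spectral matrices
#'
#' Session-level averaging of trial matrices.
#'
#' @param spectral_matrices non-empty list of `spectral_matrix` on the same
#'   grid.
#' @return a `spectral_matrix` whose `periodic` is the element-wise mean.
#' @export
session_mean_matrix <- function(spectral_matrices) {
  assert_that(length(spectral_matrices) >= 1,
              "cannot average an empty list of spectral matrices")
  f0 <- spectral_matrices[[1]]$freqs
  for (m in spectral_matrices) {
    assert_that(identical(m$freqs, f0), "grid mismatch across matrices")
  }
  acc <- Reduce(`+`, lapply(spectral_matrices, `[[`, "periodic"))
  out <- spectral_matrices[[1]]
  out$periodic <- acc / length(spectral_matrices)
  out$t_start <- NULL
  out
}
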