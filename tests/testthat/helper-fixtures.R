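# Shared fixtures, built in code.

# wrap a plain matrix as a spectral_matrix on the standard grid
mk_spectral <- function(m, participant = "p1", session = "s1",
                        condition = "task", t_start = 0) {
  dimnames(m) <- list(make_layout()$labels,
                      paste0(frequency_grid(), "Hz"))
  structure(list(periodic = m, freqs = frequency_grid(),
                 participant_id = participant, session_id = session,
                 condition = condition, t_start = t_start),
            class = "spectral_matrix")
}

rand_spectral <- function(participant = "p1", session = "s1", sd = 1,
                          shift = 0) {
  mk_spectral(matrix(stats::rnorm(32 * 27, shift, sd), 32),
              participant, session)
}

# a minimal labeled_trials object from a feature array and label matrix
mk_trials <- function(features, labels, participant = "p1", session = "s1") {
  mats <- lapply(seq_len(nrow(features)), function(i)
    mk_spectral(matrix(features[i, ], 32), participant, session,
                t_start = 2 * (i - 1)))
  meta <- data.frame(participant = rep(participant, nrow(features)),
                     session = session, condition = "task",
                     probe = seq_len(nrow(features)),
                     t_start = 2 * (seq_len(nrow(features)) - 1),
                     stringsAsFactors = FALSE)
  structure(list(matrices = mats, meta = meta, labels = labels),
            class = "labeled_trials")
}

# a 2-s test epoch at 256 Hz from a channel x time matrix
mk_epoch <- function(data, fs = 256) {
  structure(list(data = data, core_idx = seq_len(2 * fs), t_start = 0,
                 sample_rate = fs, participant_id = "p1",
                 session_id = "s1", condition = "task"),
            class = "eeg_epoch")
}

# independent brute-force Welch oracle: mean of Hamming periodograms over
# 1-s segments stepped by 0.5 s, computed with an explicit DFT sum
oracle_welch <- function(x, fs = 256) {
  n <- ncol(x)
  nseg <- fs
  starts <- seq(1, n - nseg + 1, by = nseg / 2)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  freqs <- frequency_grid()
  out <- matrix(0, nrow(x), length(freqs))
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1), drop = FALSE]
    for (fi in seq_along(freqs)) {
      f <- freqs[fi]
      e <- exp(-2i * pi * f * (0:(nseg - 1)) / nseg)
      for (ch in seq_len(nrow(x))) {
        X <- sum(seg[ch, ] * w * e)
        out[ch, fi] <- out[ch, fi] + 2 * Mod(X)^2 / (fs * sum(w^2))
      }
    }
  }
  out / length(starts)
}

# one-sided periodogram band power of a signal segment (simple FFT oracle,
# independent of the package's Welch path)
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f <= band[2]
  mean(Mod(X[sel])^2) / n
}
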