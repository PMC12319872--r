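# Signal conditioning and epoching.
#
# Pipeline order: band-pass -> notch -> segment into 2-s epochs -> common
# average reference. Artifact rejection steps used on human EEG (ICA, visual
# inspection, channel interpolation) are intentionally unsupported: inputs
# here are artifact-free synthetic recordings.

#' Construct an EEG recording container
#'
#' @param data numeric matrix, electrodes x samples, in microvolts.
#' @param sample_rate sampling rate in Hz.
#' @param layout a `channel_layout` (rows of `data` follow `layout$labels`).
#' @param probe_times numeric vector of probe onsets in seconds from start
#'   (empty for rest recordings).
#' @param condition `"task"` or `"rest"`.
#' @param participant_id,session_id identifiers.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, sample_rate, layout,
                          probe_times = numeric(0),
                          condition = c("task", "rest"),
                          participant_id = "p1", session_id = "s1") {
  condition <- match.arg(condition)
  stopifnot(is.matrix(data), nrow(data) == length(layout$labels))
  assert_that(all(is.finite(data)), "recording data must be finite")
  dur <- ncol(data) / sample_rate
  if (length(probe_times)) {
    assert_that(all(diff(probe_times) > 0),
                "probe_times must be strictly increasing")
    assert_that(all(probe_times > 0 & probe_times <= dur),
                "probe_times must lie within the recording")
  }
  rownames(data) <- layout$labels
  structure(list(data = data, sample_rate = sample_rate, layout = layout,
                 probe_times = probe_times, condition = condition,
                 participant_id = participant_id, session_id = session_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s %s/%s: %d ch x %.1f s @ %g Hz, %d probes\n",
              x$condition, x$participant_id, x$session_id, nrow(x$data),
              ncol(x$data) / x$sample_rate, x$sample_rate,
              length(x$probe_times)))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`) to every channel, giving zero phase distortion.
#'
#' @param recording an `eeg_recording`.
#' @param low_hz,high_hz pass-band edges in Hz (defaults 1 and 55).
#' @return the filtered recording.
#' @export
bandpass_filter <- function(recording, low_hz = 1, high_hz = 55) {
  nyq <- recording$sample_rate / 2
  assert_that(low_hz > 0 && high_hz > low_hz, "need 0 < low_hz < high_hz")
  assert_that(high_hz < nyq, "high cutoff must be below Nyquist")
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  recording$data <- t(apply(recording$data, 1, function(x)
    signal::filtfilt(bf, x)))
  rownames(recording$data) <- recording$layout$labels
  recording
}

#' Zero-phase notch (band-stop) filter
#'
#' Removes line noise at the listed frequencies (default 60 Hz and its
#' 120 Hz harmonic) with 2nd-order Butterworth band-stops applied
#' forward-backward. Frequencies at or above Nyquist are an error; an empty
#' list is the identity.
#'
#' @param recording an `eeg_recording`.
#' @param freqs frequencies to suppress, Hz.
#' @param width half-width of each stop band in Hz.
#' @return the filtered recording.
#' @export
notch_filter <- function(recording, freqs = c(60, 120), width = 2) {
  nyq <- recording$sample_rate / 2
  if (!length(freqs)) return(recording)
  assert_that(all(freqs < nyq), "notch frequency must be below Nyquist")
  for (f in freqs) {
    bf <- signal::butter(2, c(f - width, f + width) / nyq, type = "stop")
    recording$data <- t(apply(recording$data, 1, function(x)
      signal::filtfilt(bf, x)))
  }
  rownames(recording$data) <- recording$layout$labels
  recording
}

#' Segment a recording into non-overlapping 2-s epochs
#'
#' Tiles the recording from t = 0 with contiguous 2-s cores and attaches 1 s
#' of context on each side for spectral padding. Context that would fall
#' outside the recording is reflection-padded from the recording itself, so
#' every epoch (including the first and last) carries a full 4-s array.
#'
#' @param recording an `eeg_recording`.
#' @param core_s core epoch length, seconds (default 2).
#' @param context_s context attached on each side, seconds (default 1).
#' @return list of `eeg_epoch` objects: each has `data`
#'   (electrodes x (core+2*context) samples), `core_idx` (columns of the
#'   core), `t_start`, ids and condition. Empty list if the recording is
#'   shorter than one core.
#' @export
segment_epochs <- function(recording, core_s = 2, context_s = 1) {
  fs <- recording$sample_rate
  n <- ncol(recording$data)
  core <- round(core_s * fs)
  ctx <- round(context_s * fs)
  n_ep <- n %/% core
  if (n_ep < 1) return(list())
  # reflection-pad the whole recording once, then slice
  left <- recording$data[, ctx:1, drop = FALSE]
  right <- recording$data[, n:(n - ctx + 1), drop = FALSE]
  padded <- cbind(left, recording$data, right)
  lapply(seq_len(n_ep), function(i) {
    a <- (i - 1) * core + 1          # core start in original samples
    cols <- (a):(a + core + 2 * ctx - 1)  # shifted by ctx into padded
    structure(list(
      data = padded[, cols, drop = FALSE],
      core_idx = (ctx + 1):(ctx + core),
      t_start = (i - 1) * core_s,
      sample_rate = fs,
      participant_id = recording$participant_id,
      session_id = recording$session_id,
      condition = recording$condition
    ), class = "eeg_epoch")
  })
}

#' Select the epochs in the pre-probe analysis window
#'
#' Returns the epochs whose 2-s cores lie fully inside
#' `[probe_time - window_s, probe_time)`. With the default 12-s window and
#' 2-s tiling from t = 0 this is 6 epochs whenever alignment and recording
#' length permit; near the recording start the available subset is returned.
#'
#' @param epochs list of `eeg_epoch` from [segment_epochs()].
#' @param probe_time probe onset in seconds.
#' @param window_s analysis window length (8, 12 or 16 s).
#' @return the selected epochs, in time order.
#' @export
preprobe_window <- function(epochs, probe_time, window_s = 12) {
  stopifnot(window_s %in% c(8, 12, 16))
  keep <- vapply(epochs, function(e) {
    core_len <- length(e$core_idx) / e$sample_rate
    e$t_start >= probe_time - window_s && (e$t_start + core_len) <= probe_time
  }, logical(1))
  epochs[keep]
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at each sample. Idempotent and invariant to
#' adding a common offset.
#'
#' @param epoch an `eeg_epoch` (or any electrodes x time matrix-bearing
#'   object with a `data` field).
#' @return the re-referenced epoch.
#' @export
common_average_reference <- function(epoch) {
  assert_that(nrow(epoch$data) >= 2, "CAR requires at least 2 channels")
  epoch$data <- sweep(epoch$data, 2, colMeans(epoch$data))
  epoch
}

#' Run the full preprocessing chain on a recording
#'
#' band-pass -> notch -> epoch segmentation -> common average reference.
#'
#' @inheritParams bandpass_filter
#' @param notch_freqs notch frequencies (set `numeric(0)` to skip).
#' @param window/core handled by [segment_epochs()] defaults.
#' @return list of re-referenced `eeg_epoch` objects.
#' @export
preprocess_recording <- function(recording, low_hz = 1, high_hz = 55,
                                 notch_freqs = c(60, 120)) {
  rec <- bandpass_filter(recording, low_hz, high_hz)
  rec <- notch_filter(rec, notch_freqs)
  lapply(segment_epochs(rec), common_average_reference)
}
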