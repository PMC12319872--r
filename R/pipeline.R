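# In-memory pipeline helpers: from simulated sessions to labeled trials
# without touching disk. These are the programmatic counterpart of the
# staged CLI pipeline and are what the examples, tests, and analysis
# scripts use.

#' Labeled trials for one simulated task session
#'
#' Preprocesses the recording (band-pass, notch, epoch, common average
#' reference), computes periodic spectral matrices for the epochs inside
#' each pre-probe window only, and attaches the probe's dichotomized
#' labels.
#'
#' @param session a session bundle from [simulate_session()].
#' @param window_s pre-probe analysis window (8, 12 or 16 s).
#' @param notch_freqs notch frequencies passed to the preprocessing chain.
#' @return a `labeled_trials` object.
#' @export
session_trials <- function(session, window_s = 12, notch_freqs = c(60, 120)) {
  epochs <- preprocess_recording(session$recording,
                                 notch_freqs = notch_freqs)
  probe_times <- session$recording$probe_times
  keep <- unique(unlist(lapply(probe_times, function(pt) {
    which(vapply(epochs, function(e) {
      core_len <- length(e$core_idx) / e$sample_rate
      e$t_start >= pt - window_s && (e$t_start + core_len) <= pt
    }, logical(1)))
  })))
  mats <- lapply(epochs[sort(keep)], epoch_spectral_matrix)
  assemble_trials(mats, session$reports, window_s = window_s)
}

#' Labeled trials for one simulated rest block
#'
#' All 2-s epochs of the block inherit the retrospective report's labels.
#'
#' @param rest_block a bundle from [simulate_rest()].
#' @inheritParams session_trials
#' @return a `labeled_trials` object.
#' @export
rest_trials <- function(rest_block, notch_freqs = c(60, 120)) {
  epochs <- preprocess_recording(rest_block$recording,
                                 notch_freqs = notch_freqs)
  mats <- lapply(epochs, epoch_spectral_matrix)
  label_rest(mats, rest_block$report)
}

#' Labeled task trials for a whole simulated cohort
#'
#' @param cohort a `synth_cohort` from [simulate_cohort()].
#' @param window_s pre-probe analysis window.
#' @return named list of per-session `labeled_trials` (names "pXX_sYY").
#' @export
cohort_task_trials <- function(cohort, window_s = 12) {
  lapply(cohort$task, session_trials, window_s = window_s)
}

#' Labeled rest trials for a whole simulated cohort
#' @inheritParams cohort_task_trials
#' @return named list of per-block `labeled_trials`.
#' @export
cohort_rest_trials <- function(cohort) {
  lapply(cohort$rest, rest_trials)
}
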