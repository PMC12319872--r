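# Synthetic EEG cohort generator.
#
# Emulates the study design: per session ~80 min of continuous 32-channel
# 256-Hz "task" EEG with ~35 jittered thought probes (gaps uniform on
# 90-150 s) plus two 5-min rest blocks; 1/f background with per-participant
# aperiodic parameters, band-limited oscillatory peaks with fixed
# topographies, and planted thought-dimension effects: oscillatory amplitude
# in an effect's electrode x band region is scaled by (1 + gain*sign*latent)
# during each pre-probe window. Likert reports derive from the same latents
# with reporting noise, so ground truth for every downstream stage is known.

#' Specify a planted thought-dimension effect
#'
#' @param dimension one of [thought_dimensions()].
#' @param electrodes electrode labels carrying the effect.
#' @param band numeric `c(low_hz, high_hz)` inside 4-30 Hz.
#' @param gain multiplicative amplitude factor per unit latent (>= 0).
#' @param sign +1 (upper-end ratings raise power) or -1.
#' @param amplitude baseline oscillatory amplitude of the effect source, uV.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(dimension, electrodes, band, gain = 0.3, sign = 1,
                        amplitude = 2) {
  assert_that(dimension %in% thought_dimensions(), "unknown dimension")
  assert_that(length(electrodes) >= 1, "effect needs at least one electrode")
  assert_that(band[1] >= 4 && band[2] <= 30 && band[1] <= band[2],
              "effect band must lie within [4, 30] Hz")
  assert_that(gain >= 0, "gain must be non-negative")
  assert_that(sign %in% c(-1, 1), "sign must be +1 or -1")
  structure(list(dimension = dimension, electrodes = electrodes,
                 band = band, gain = gain, sign = sign,
                 amplitude = amplitude),
            class = "effect_spec")
}

# electrode groups used by the default effect topographies
.electrode_groups <- function() {
  list(
    posterior = c("P7", "P3", "Pz", "P4", "P8", "PO3", "PO4",
                  "O1", "Oz", "O2"),
    frontal = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8"),
    central = c("FC1", "FC2", "C3", "Cz", "C4", "CP1", "CP2"),
    frontocentral = c("F3", "Fz", "F4", "FC1", "FC2", "Cz", "C3", "C4"),
    widespread = make_layout()$labels
  )
}

#' Default planted effects
#'
#' Qualitative directions follow the task-condition findings this pipeline
#' is designed to probe: e.g. off-task thought raises posterior low-alpha
#' power, goal-directed thought lowers alpha. All regions, bands, gains and
#' signs are plain configuration, not hard-coded behavior.
#'
#' @param gain gain applied to every default effect.
#' @return list of `effect_spec`.
#' @export
default_effects <- function(gain = 0.3) {
  g <- .electrode_groups()
  list(
    effect_spec("off_task",      g$posterior,     c(8, 9),   gain,  1),
    effect_spec("internal",      c(g$central, g$posterior), c(8, 9), gain, 1),
    effect_spec("freely_moving", g$frontocentral, c(8, 9),   gain,  1),
    effect_spec("sticky",        g$central,       c(6, 7),   gain,  1),
    effect_spec("goal_directed", c(g$frontal, g$posterior), c(8, 13), gain, -1),
    effect_spec("self",          g$frontal,       c(8, 9),   gain,  1),
    effect_spec("other",         g$widespread,    c(14, 20), gain,  1)
  )
}

# default inter-dimension correlation of the latent thought states:
# moderate positive coupling among content/dynamics dimensions, negative
# between off-task and goal-directed thought.
.default_correlation <- function() {
  d <- thought_dimensions()
  R <- diag(7)
  dimnames(R) <- list(d, d)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("off_task", "freely_moving", 0.4)
  set_r("off_task", "internal", 0.4)
  set_r("off_task", "goal_directed", -0.3)
  set_r("freely_moving", "internal", 0.3)
  set_r("self", "internal", 0.3)
  set_r("self", "other", 0.2)
  set_r("sticky", "goal_directed", 0.2)
  R
}

#' Build a synthetic-cohort configuration
#'
#' Defaults mirror the emulated study: 7 participants x 7 sessions,
#' ~80-minute task blocks with 35 probes at 90-150 s gaps, two 5-minute rest
#' blocks per session, 256 Hz sampling, 1/f background with per-participant
#' offset/exponent, and the [default_effects()] planted at moderate gain.
#'
#' @param n_participants,n_sessions cohort size.
#' @param task_duration nominal task length, seconds.
#' @param n_probes probes per session.
#' @param probe_gap `c(min, max)` inter-probe gap, seconds.
#' @param rest_duration rest block length, seconds.
#' @param sample_rate sampling rate, Hz.
#' @param aperiodic list with `offset` and `exponent` ranges (uniform,
#'   drawn once per participant). Offset is log10(uV^2/Hz) at 1 Hz.
#' @param oscillators list of base peaks, each
#'   `list(center, bandwidth, electrodes, amplitude)`.
#' @param effects list of [effect_spec()].
#' @param correlation 7x7 latent correlation matrix (symmetric PD, unit
#'   diagonal).
#' @param report_noise SD of the Gaussian rating noise.
#' @param effect_window_s length of the pre-probe window in which latents
#'   modulate amplitude, seconds.
#' @param seed root seed for the cohort.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_participants = 7, n_sessions = 7,
                         task_duration = 4800, n_probes = 35,
                         probe_gap = c(90, 150), rest_duration = 300,
                         sample_rate = 256,
                         aperiodic = list(offset = c(0.5, 1.5),
                                          exponent = c(0.8, 1.4)),
                         oscillators = NULL, effects = default_effects(),
                         correlation = .default_correlation(),
                         report_noise = 0.5, effect_window_s = 12,
                         seed = 1L) {
  g <- .electrode_groups()
  if (is.null(oscillators)) {
    oscillators <- list(
      list(center = 10, bandwidth = 2, electrodes = g$posterior,
           amplitude = 4),
      list(center = 6, bandwidth = 2, electrodes = g$frontal,
           amplitude = 2),
      list(center = 18, bandwidth = 6, electrodes = g$central,
           amplitude = 1.5)
    )
  }
  assert_that(probe_gap[1] >= 16,
              "minimum probe gap must cover the longest analysis window")
  assert_that(probe_gap[1] < probe_gap[2], "probe_gap must be an interval")
  assert_that(n_probes * probe_gap[1] <= task_duration + probe_gap[2] * 2,
              "n_probes incompatible with task_duration and probe gaps")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  assert_that(all(ev > 1e-10) && all(abs(diag(correlation) - 1) < 1e-12),
              "correlation must be symmetric positive-definite with unit diagonal")
  lay <- make_layout()
  for (e in effects) {
    assert_that(all(e$electrodes %in% lay$labels),
                "effect references unknown electrodes")
  }
  structure(list(
    n_participants = n_participants, n_sessions = n_sessions,
    task_duration = task_duration, n_probes = n_probes,
    probe_gap = probe_gap, rest_duration = rest_duration,
    sample_rate = sample_rate, aperiodic = aperiodic,
    oscillators = oscillators, effects = effects,
    correlation = correlation, report_noise = report_noise,
    effect_window_s = effect_window_s, seed = as.integer(seed),
    layout = lay
  ), class = "synth_config")
}

#' Simulate latent thought-state trajectories
#'
#' Draws one 7-vector per pre-probe window: marginally standard normal with
#' the configured inter-dimension correlation, piecewise-constant over each
#' window.
#'
#' @param config a `synth_config` (its `correlation` is used).
#' @param n_windows number of windows (probes).
#' @param seed RNG seed.
#' @return `n_windows` x 7 matrix, columns named by dimension.
#' @export
simulate_latents <- function(config, n_windows, seed = NULL) {
  R <- config$correlation
  ch <- tryCatch(chol(R), error = function(e)
    stop("latent correlation matrix is not positive-definite", call. = FALSE))
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_windows * ncol(R)), n_windows)
    lat <- z %*% ch
    colnames(lat) <- thought_dimensions()
    lat
  })
}

#' Map a latent value to a 7-point Likert rating
#'
#' `rating = round(4 + 1.5 * latent + noise)` clipped to 1..7, with
#' Gaussian reporting noise.
#'
#' @param latent_value numeric vector of latents.
#' @param report_noise SD of the rating noise.
#' @param seed RNG seed.
#' @return integer ratings in 1..7.
#' @export
latent_to_rating <- function(latent_value, report_noise = 0.5, seed = NULL) {
  with_seed(seed, {
    noise <- if (report_noise > 0) {
      stats::rnorm(length(latent_value), 0, report_noise)
    } else 0
    r <- round(4 + 1.5 * latent_value + noise)
    as.integer(pmin(7L, pmax(1L, r)))
  })
}

# 1/f-shaped background noise: white noise spectrally shaped by FFT so the
# one-sided PSD is 10^offset * f^(-exponent) uV^2/Hz.
.aperiodic_noise <- function(n, fs, offset, exponent) {
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  fk <- pmin(f, fs - f)            # fold to [0, fs/2]
  fk <- pmax(fk, 0.5)              # avoid the DC singularity
  gain <- sqrt(10^offset * fk^(-exponent) * fs / 2)
  Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
}

# narrowband source: white noise with a Gaussian spectral envelope centered
# at `center` Hz (SD = bandwidth/2), normalized to unit variance.
.narrowband_noise <- function(n, fs, center, bandwidth) {
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  fk <- pmin(f, fs - f)
  env <- exp(-((fk - center)^2) / (2 * (bandwidth / 2)^2))
  x <- Re(stats::fft(stats::fft(w) * env, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# amplitude envelope: 1 everywhere, (1 + gain*sign*latent) clipped at 0
# inside each pre-probe window
.effect_envelope <- function(n, fs, probe_times, window_s, scale) {
  a <- rep(1, n)
  for (i in seq_along(probe_times)) {
    i0 <- max(1L, floor((probe_times[i] - window_s) * fs) + 1L)
    i1 <- min(n, ceiling(probe_times[i] * fs))
    a[i0:i1] <- max(0, scale[i])
  }
  a
}

# shared signal synthesis for task and rest blocks.
# latents: n_windows x 7; for rest, one row and windows spanning the block.
.synthesize_signal <- function(config, n, fs, ap, probe_times, window_s,
                               latents) {
  lay <- config$layout
  n_ch <- length(lay$labels)
  data <- matrix(0, n_ch, n)
  rownames(data) <- lay$labels
  for (ch in seq_len(n_ch)) {
    data[ch, ] <- .aperiodic_noise(n, fs, ap$offset, ap$exponent)
  }
  for (osc in config$oscillators) {
    src <- .narrowband_noise(n, fs, osc$center, osc$bandwidth)
    idx <- match(osc$electrodes, lay$labels)
    for (ch in idx) data[ch, ] <- data[ch, ] + osc$amplitude * src
  }
  for (eff in config$effects) {
    center <- mean(eff$band)
    bw <- max(1, diff(eff$band))
    src <- .narrowband_noise(n, fs, center, bw)
    scale <- 1 + eff$gain * eff$sign * latents[, eff$dimension]
    env <- .effect_envelope(n, fs, probe_times, window_s, scale)
    mod_src <- src * env
    idx <- match(eff$electrodes, lay$labels)
    for (ch in idx) data[ch, ] <- data[ch, ] + eff$amplitude * mod_src
  }
  data
}

# ground-truth electrode x frequency mask for each effect, on the 1-Hz grid
.effect_masks <- function(config) {
  lay <- config$layout
  freqs <- frequency_grid()
  masks <- list()
  for (eff in config$effects) {
    m <- matrix(FALSE, length(lay$labels), length(freqs),
                dimnames = list(lay$labels, paste0(freqs, "Hz")))
    bins <- freqs >= eff$band[1] & freqs <= eff$band[2]
    m[match(eff$electrodes, lay$labels), bins] <- TRUE
    masks[[eff$dimension]] <- m
  }
  masks
}

#' Simulate one task session
#'
#' Generates the continuous EEG, jittered probe schedule, per-window latents,
#' probe reports, and the ground-truth record of planted effects. The
#' session ends at the last probe, so exactly `n_probes` probes fit with
#' every gap inside the configured range.
#'
#' @param config a `synth_config`.
#' @param participant_id,session_id identifiers (integers or strings).
#' @param seed RNG seed for this session.
#' @param aperiodic_params optional `list(offset, exponent)`; drawn from the
#'   configured ranges when `NULL` (cohort simulation draws them once per
#'   participant and passes them here).
#' @return `list(recording, reports, ground_truth)` where `reports` is a
#'   data.frame (one row per probe) and `ground_truth` carries latents and
#'   effect masks.
#' @export
simulate_session <- function(config, participant_id = "p1",
                             session_id = "s1", seed = NULL,
                             aperiodic_params = NULL) {
  fs <- config$sample_rate
  with_seed(seed, {
    if (is.null(aperiodic_params)) {
      aperiodic_params <- list(
        offset = stats::runif(1, config$aperiodic$offset[1],
                              config$aperiodic$offset[2]),
        exponent = stats::runif(1, config$aperiodic$exponent[1],
                                config$aperiodic$exponent[2]))
    }
    gaps <- stats::runif(config$n_probes, config$probe_gap[1],
                         config$probe_gap[2])
    probe_times <- cumsum(gaps)
    duration <- ceiling(probe_times[length(probe_times)])
    n <- duration * fs
    latents <- simulate_latents(config, config$n_probes)
    data <- .synthesize_signal(config, n, fs, aperiodic_params, probe_times,
                               config$effect_window_s, latents)
    ratings <- matrix(NA_integer_, config$n_probes, 7,
                      dimnames = list(NULL, thought_dimensions()))
    for (d in thought_dimensions()) {
      ratings[, d] <- latent_to_rating(latents[, d], config$report_noise)
    }
    activities <- sample(c("reading", "writing", "watching videos",
                           "browsing", "cognitively demanding", "nothing"),
                         config$n_probes, replace = TRUE,
                         prob = c(.32, .14, .19, .11, .23, .01))
    rec <- new_recording(data, fs, config$layout, probe_times, "task",
                         as.character(participant_id),
                         as.character(session_id))
    reports <- data.frame(
      participant = as.character(participant_id),
      session = as.character(session_id),
      condition = "task",
      probe_time_s = probe_times,
      scope = "momentary",
      activity = activities,
      stringsAsFactors = FALSE
    )
    reports <- cbind(reports, as.data.frame(ratings))
    gt <- list(latents = latents, probe_times = probe_times,
               aperiodic = aperiodic_params,
               effect_masks = .effect_masks(config))
    list(recording = rec, reports = reports, ground_truth = gt)
  })
}

#' Simulate one resting-state block
#'
#' A 5-minute (configurable) recording with the same background and
#' oscillators as the task; a single latent 7-vector holds for the whole
#' block and yields one retrospective report. The activity and task-
#' relatedness questions are not asked at rest, so `activity` is `NA` and
#' the `off_task` rating is `NA`.
#'
#' @inheritParams simulate_session
#' @param block rest block index within the session (1 or 2).
#' @return `list(recording, report, ground_truth)`.
#' @export
simulate_rest <- function(config, participant_id = "p1", session_id = "s1",
                          seed = NULL, aperiodic_params = NULL, block = 1) {
  fs <- config$sample_rate
  with_seed(seed, {
    if (is.null(aperiodic_params)) {
      aperiodic_params <- list(
        offset = stats::runif(1, config$aperiodic$offset[1],
                              config$aperiodic$offset[2]),
        exponent = stats::runif(1, config$aperiodic$exponent[1],
                                config$aperiodic$exponent[2]))
    }
    n <- config$rest_duration * fs
    latents <- simulate_latents(config, 1)
    # the block-long "window": one probe at the end covering the whole block
    data <- .synthesize_signal(config, n, fs, aperiodic_params,
                               probe_times = config$rest_duration,
                               window_s = config$rest_duration,
                               latents = latents)
    ratings <- vapply(thought_dimensions(), function(d)
      latent_to_rating(latents[1, d], config$report_noise), integer(1))
    ratings["off_task"] <- NA_integer_
    rec <- new_recording(data, fs, config$layout, numeric(0), "rest",
                         as.character(participant_id),
                         as.character(session_id))
    report <- data.frame(
      participant = as.character(participant_id),
      session = as.character(session_id),
      condition = "rest",
      probe_time_s = config$rest_duration,
      scope = "retrospective",
      activity = NA_character_,
      stringsAsFactors = FALSE
    )
    report <- cbind(report, as.data.frame(t(ratings)))
    report$block <- block
    gt <- list(latents = latents, aperiodic = aperiodic_params,
               effect_masks = .effect_masks(config))
    list(recording = rec, report = report, ground_truth = gt)
  })
}

#' Simulate a full cohort
#'
#' `n_participants x n_sessions` task sessions plus two rest blocks per
#' session. Aperiodic parameters are drawn once per participant and reused
#' across that participant's sessions. All randomness derives from
#' `config$seed` via named substreams, so the cohort is fully reproducible.
#'
#' @param config a `synth_config`.
#' @param include_rest generate the two rest blocks per session (default
#'   TRUE); disable when only task data are needed.
#' @return a `synth_cohort`: `list(task = <list of session bundles>,
#'   rest = <list of rest bundles>, participants = <aperiodic draws>,
#'   config = config)`.
#' @export
simulate_cohort <- function(config, include_rest = TRUE) {
  task <- list()
  rest <- list()
  participants <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("p%02d", p)
    ap <- with_seed(stage_seed(config$seed, paste0("aperiodic_", pid)), list(
      offset = stats::runif(1, config$aperiodic$offset[1],
                            config$aperiodic$offset[2]),
      exponent = stats::runif(1, config$aperiodic$exponent[1],
                              config$aperiodic$exponent[2])))
    participants[[pid]] <- ap
    for (s in seq_len(config$n_sessions)) {
      sid <- sprintf("s%02d", s)
      key <- paste0(pid, "_", sid)
      task[[key]] <- simulate_session(
        config, pid, sid, seed = stage_seed(config$seed, paste0("task_", key)),
        aperiodic_params = ap)
      if (include_rest) for (b in 1:2) {
        rkey <- paste0(key, "_r", b)
        rest[[rkey]] <- simulate_rest(
          config, pid, sid,
          seed = stage_seed(config$seed, paste0("rest_", rkey)),
          aperiodic_params = ap, block = b)
      }
    }
  }
  structure(list(task = task, rest = rest, participants = participants,
                 config = config),
            class = "synth_cohort")
}
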