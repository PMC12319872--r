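# Plain-text artifact I/O: probe reports and labels as CSV, epoch features
# as one CSV per session, ground truth and cluster results as JSON.

#' Write / read the probe-report table
#'
#' Columns: participant, session, condition, probe_time_s, scope, activity,
#' then one column per thought dimension.
#'
#' @param reports data.frame of probe reports.
#' @param path CSV path.
#' @return the path / the data.frame.
#' @export
write_reports <- function(reports, path) {
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write epoch-level spectral features for one session
#'
#' One row per epoch: participant, session, condition, t_start, then 864
#' feature columns named `<electrode>_<freq>Hz` (electrode fastest, matching
#' [trial_matrix()]).
#'
#' @param spectral_matrices list of epoch-level `spectral_matrix`.
#' @param path CSV path.
#' @export
write_features <- function(spectral_matrices, path) {
  m1 <- spectral_matrices[[1]]
  labs <- rownames(m1$periodic)
  freqs <- m1$freqs
  feat_names <- as.vector(outer(labs, freqs, function(l, f)
    paste0(l, "_", f, "Hz")))
  feats <- t(vapply(spectral_matrices, function(m) as.vector(m$periodic),
                    numeric(length(feat_names))))
  colnames(feats) <- feat_names
  meta <- data.frame(
    participant = vapply(spectral_matrices, `[[`, character(1),
                         "participant_id"),
    session = vapply(spectral_matrices, `[[`, character(1), "session_id"),
    condition = vapply(spectral_matrices, `[[`, character(1), "condition"),
    t_start = vapply(spectral_matrices, `[[`, numeric(1), "t_start"),
    stringsAsFactors = FALSE)
  utils::write.csv(cbind(meta, feats), path, row.names = FALSE)
  invisible(path)
}

#' Read a session feature CSV back into spectral matrices
#'
#' @param path CSV written by [write_features()].
#' @return list of `spectral_matrix`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("participant", "session", "condition", "t_start")
  feat_cols <- setdiff(colnames(df), meta_cols)
  labs <- unique(sub("_[0-9]+Hz$", "", feat_cols))
  freqs <- sort(unique(as.integer(sub("^.*_([0-9]+)Hz$", "\\1", feat_cols))))
  lapply(seq_len(nrow(df)), function(i) {
    periodic <- matrix(as.numeric(df[i, feat_cols]), length(labs),
                       length(freqs),
                       dimnames = list(labs, paste0(freqs, "Hz")))
    structure(list(periodic = periodic, freqs = freqs,
                   participant_id = df$participant[i],
                   session_id = df$session[i],
                   condition = df$condition[i],
                   t_start = df$t_start[i]),
              class = "spectral_matrix")
  })
}

#' Write the ground-truth sidecar for one simulated session
#' @param ground_truth list from [simulate_session()] / [simulate_rest()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$effect_masks <- lapply(gt$effect_masks, function(m) {
    list(electrodes = rownames(m)[rowSums(m) > 0],
         freqs = frequency_grid()[colSums(m) > 0])
  })
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth sidecar
#' @param path JSON path from [write_ground_truth()].
#' @return list with `latents`, `probe_times`, `aperiodic`, `effect_masks`
#'   (reconstructed logical matrices).
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  lay <- make_layout()
  freqs <- frequency_grid()
  gt$effect_masks <- lapply(gt$effect_masks, function(mk) {
    m <- matrix(FALSE, length(lay$labels), length(freqs),
                dimnames = list(lay$labels, paste0(freqs, "Hz")))
    m[match(mk$electrodes, lay$labels),
      match(mk$freqs, freqs)] <- TRUE
    m
  })
  gt
}

#' Export a cluster result as JSON
#'
#' Cluster members are reported by electrode label and frequency in Hz.
#'
#' @param result a `cluster_result`.
#' @param path JSON path.
#' @export
write_cluster_result <- function(result, path) {
  n_el <- nrow(result$t_map)
  freqs <- frequency_grid()
  clusters <- lapply(result$clusters, function(cl) {
    el <- (cl$cells - 1) %% n_el + 1
    bin <- (cl$cells - 1) %/% n_el + 1
    list(members = data.frame(electrode = result$labels[el],
                              freq_hz = freqs[bin]),
         mass = cl$mass, sign = cl$sign, p = cl$p)
  })
  jsonlite::write_json(
    list(threshold_t = result$threshold_t, n_perm = result$n_perm,
         n_pairs = result$n_pairs, seed = result$seed, clusters = clusters),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
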