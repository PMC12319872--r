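# Likert dichotomization, trial labeling, and inclusion/exclusion rules.

#' Dichotomize a 7-point Likert rating
#'
#' Ratings 1-3 map to `"lower"`, 5-7 to `"upper"`, the midpoint 4 is
#' `"discarded"`. Missing ratings (questions not asked, e.g. task-
#' relatedness at rest) are `"discarded"`. Vectorized.
#'
#' @param rating integer rating(s) in 1..7 (or NA).
#' @return character vector of classes.
#' @export
dichotomize <- function(rating) {
  ok <- is.na(rating) | (rating %in% 1:7)
  assert_that(all(ok), "ratings must be integers in 1..7 or NA")
  out <- rep("discarded", length(rating))
  out[!is.na(rating) & rating <= 3] <- "lower"
  out[!is.na(rating) & rating >= 5] <- "upper"
  out
}

#' Assemble labeled trials from session features and probe reports
#'
#' Each epoch-level spectral matrix whose 2-s core lies inside a probe's
#' pre-probe window becomes one trial carrying that probe's dichotomized
#' rating on every dimension. Task condition only; probes with no available
#' epochs are skipped with a warning.
#'
#' @param spectral_matrices list of epoch-level `spectral_matrix` for one
#'   session (each with a `t_start`).
#' @param reports data.frame of that session's probe reports (columns
#'   `probe_time_s` plus one column per dimension).
#' @param window_s pre-probe window length (8, 12 or 16 s).
#' @param core_s epoch core length, seconds.
#' @return a `labeled_trials` object: `matrices` (list of spectral_matrix),
#'   `meta` (data.frame: participant, session, condition, probe, t_start),
#'   `labels` (trials x 7 character matrix of classes).
#' @export
assemble_trials <- function(spectral_matrices, reports, window_s = 12,
                            core_s = 2) {
  stopifnot(window_s %in% c(8, 12, 16))
  dims <- thought_dimensions()
  if (nrow(reports) == 0 || length(spectral_matrices) == 0) {
    return(.empty_trials())
  }
  t0 <- vapply(spectral_matrices, `[[`, numeric(1), "t_start")
  mats <- list(); meta <- list(); labs <- list()
  for (i in seq_len(nrow(reports))) {
    pt <- reports$probe_time_s[i]
    sel <- which(t0 >= pt - window_s & t0 + core_s <= pt)
    if (!length(sel)) {
      warning(sprintf("probe at %.1f s has no feature epochs; skipped", pt))
      next
    }
    cls <- dichotomize(unlist(reports[i, dims]))
    for (j in sel) {
      mats[[length(mats) + 1L]] <- spectral_matrices[[j]]
      m <- spectral_matrices[[j]]
      meta[[length(meta) + 1L]] <- data.frame(
        participant = m$participant_id, session = m$session_id,
        condition = m$condition, probe = i, t_start = m$t_start,
        stringsAsFactors = FALSE)
      labs[[length(labs) + 1L]] <- cls
    }
  }
  if (!length(mats)) return(.empty_trials())
  labels <- do.call(rbind, labs)
  colnames(labels) <- dims
  structure(list(matrices = mats, meta = do.call(rbind, meta),
                 labels = labels),
            class = "labeled_trials")
}

.empty_trials <- function() {
  structure(list(matrices = list(),
                 meta = data.frame(participant = character(0),
                                   session = character(0),
                                   condition = character(0),
                                   probe = integer(0),
                                   t_start = numeric(0)),
                 labels = matrix(character(0), 0, 7,
                                 dimnames = list(NULL, thought_dimensions()))),
            class = "labeled_trials")
}

#' @export
print.labeled_trials <- function(x, ...) {
  cat(sprintf("<labeled_trials> %d trials\n", length(x$matrices)))
  invisible(x)
}

#' Combine labeled-trial sets
#' @param ... `labeled_trials` objects.
#' @return a single `labeled_trials`.
#' @export
bind_trials <- function(...) {
  parts <- Filter(function(p) length(p$matrices) > 0, list(...))
  if (!length(parts)) return(.empty_trials())
  structure(list(
    matrices = do.call(c, lapply(parts, `[[`, "matrices")),
    meta = do.call(rbind, lapply(parts, `[[`, "meta")),
    labels = do.call(rbind, lapply(parts, `[[`, "labels"))
  ), class = "labeled_trials")
}

#' Session-level upper/lower condition pair for one dimension
#'
#' Averages a session's trial matrices separately for the upper and lower
#' end of the given dimension. A session lacking trials on either end is
#' excluded (returns `NULL`).
#'
#' @param trials `labeled_trials` from a single session.
#' @param dimension one of [thought_dimensions()].
#' @return `NULL` (exclusion) or a list with `upper` and `lower`, each
#'   `list(matrix = spectral_matrix, n_trials = count)`.
#' @export
session_condition_pairs <- function(trials, dimension) {
  cls <- trials$labels[, dimension]
  up <- which(cls == "upper")
  lo <- which(cls == "lower")
  if (!length(up) || !length(lo)) return(NULL)
  mk <- function(idx, end) {
    m <- session_mean_matrix(trials$matrices[idx])
    m$dimension <- dimension
    m$end <- end
    list(matrix = m, n_trials = length(idx))
  }
  list(upper = mk(up, "upper"), lower = mk(lo, "lower"))
}

#' Label rest epochs from the retrospective report
#'
#' Every 2-s rest epoch inherits the block's single retrospective
#' dichotomized label on each dimension.
#'
#' @param rest_matrices list of epoch-level `spectral_matrix` for one rest
#'   block.
#' @param retrospective_report one-row data.frame with dimension columns.
#' @return a `labeled_trials` object.
#' @export
label_rest <- function(rest_matrices, retrospective_report) {
  stopifnot(nrow(retrospective_report) == 1)
  dims <- thought_dimensions()
  if (!length(rest_matrices)) return(.empty_trials())
  cls <- dichotomize(unlist(retrospective_report[1, dims]))
  labels <- matrix(rep(cls, each = length(rest_matrices)),
                   nrow = length(rest_matrices),
                   dimnames = list(NULL, dims))
  meta <- do.call(rbind, lapply(rest_matrices, function(m) data.frame(
    participant = m$participant_id, session = m$session_id,
    condition = m$condition, probe = 1L, t_start = m$t_start,
    stringsAsFactors = FALSE)))
  structure(list(matrices = rest_matrices, meta = meta, labels = labels),
            class = "labeled_trials")
}

#' Cohort-wide rest-dimension exclusions
#'
#' A dimension is excluded for the whole cohort if any participant lacks
#' trials on one end of it across all of their rest blocks.
#'
#' @param rest_labels data.frame with a `participant` column and one column
#'   per dimension holding classes (`"lower"`, `"upper"`, `"discarded"`),
#'   one row per rest trial (or per rest block; broadcasting does not change
#'   the outcome).
#' @return character vector of excluded dimensions (possibly empty).
#' @export
cohort_rest_exclusions <- function(rest_labels) {
  dims <- intersect(thought_dimensions(), colnames(rest_labels))
  excluded <- character(0)
  for (d in dims) {
    for (p in unique(rest_labels$participant)) {
      cls <- rest_labels[rest_labels$participant == p, d]
      if (!any(cls == "upper") || !any(cls == "lower")) {
        excluded <- c(excluded, d)
        break
      }
    }
  }
  excluded
}

#' Top correlated dimensions per participant
#'
#' For each participant, Pearson-correlates the Likert ratings of the target
#' dimension with every other dimension within each session, averages the
#' correlations across sessions via Fisher's z, and returns the three
#' dimensions with the largest absolute mean correlation. Zero-variance
#' rating vectors yield an undefined correlation, treated as 0 with a
#' warning.
#'
#' @param reports probe-report data.frame (columns `participant`, `session`,
#'   one per dimension).
#' @param target_dimension dimension of interest.
#' @return named list: per participant, a character vector of 3 dimensions.
#' @export
top_correlated_dimensions <- function(reports, target_dimension) {
  dims <- setdiff(thought_dimensions(), target_dimension)
  out <- list()
  for (p in unique(reports$participant)) {
    rp <- reports[reports$participant == p, , drop = FALSE]
    zsum <- stats::setNames(numeric(length(dims)), dims)
    zn <- stats::setNames(numeric(length(dims)), dims)
    for (s in unique(rp$session)) {
      rs <- rp[rp$session == s, , drop = FALSE]
      x <- rs[[target_dimension]]
      if (length(x) < 2) next
      for (d in dims) {
        y <- rs[[d]]
        if (stats::sd(x, na.rm = TRUE) == 0 || is.na(stats::sd(y, na.rm = TRUE)) ||
            stats::sd(y, na.rm = TRUE) == 0) {
          warning(sprintf(
            "zero-variance ratings (%s or %s) in session %s; correlation set to 0",
            target_dimension, d, s))
          r <- 0
        } else {
          r <- stats::cor(x, y, use = "complete.obs")
          if (is.na(r)) r <- 0
        }
        r <- max(-0.999999, min(0.999999, r))
        zsum[d] <- zsum[d] + atanh(r)
        zn[d] <- zn[d] + 1
      }
    }
    zmean <- ifelse(zn > 0, zsum / pmax(zn, 1), 0)
    rmean <- tanh(zmean)
    top <- names(sort(abs(rmean), decreasing = TRUE))[1:3]
    attr(top, "r") <- rmean
    out[[p]] <- top
  }
  out
}
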