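# Orchestration: configuration, staged pipeline, artifact tree, reporting.
#
# Stages: simulate -> features -> label -> cluster-test -> lmm ->
# similarity -> classify -> report. Every stage derives its randomness from
# the run's root seed via a named substream (stage_seed), so stages can be
# rerun independently and the whole run is byte-reproducible.

#' Build a run configuration
#'
#' @param synth list of [synth_config()] arguments (scaled-down cohorts are
#'   configured here; the generator defaults emulate the full study design).
#' @param window_s pre-probe analysis window (8, 12 or 16 s).
#' @param cluster list: `n_perm`, `cluster_alpha`, `distance_threshold`.
#' @param scnn list of [scnn_config()] arguments.
#' @param classify list: `n_iterations`, `min_class_trials`, `loso`,
#'   `dimensions` (NULL = all).
#' @param seed global seed.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = list(), window_s = 12,
                       cluster = list(), scnn = list(),
                       classify = list(), seed = 1L) {
  cl <- utils::modifyList(list(n_perm = 1000, cluster_alpha = 0.05,
                               distance_threshold = 0.55), cluster)
  cf <- utils::modifyList(list(n_iterations = 25, min_class_trials = 50,
                               loso = FALSE, dimensions = NULL), classify)
  structure(list(synth = synth, window_s = window_s, cluster = cl,
                 scnn = scnn, classify = cf, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with any subset of [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), sprintf("missing config file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j[intersect(names(j), names(formals(run_config)))])
}

.resolve_synth <- function(cfg) {
  args <- cfg$synth
  args$seed <- args$seed %||% stage_seed(cfg$seed, "simulate")
  do.call(synth_config, args)
}

.manifest_update <- function(out, stage, info) {
  path <- file.path(out, "manifest.json")
  man <- if (file.exists(path)) jsonlite::read_json(path) else
    list(package = "thoughtprobe",
         version = as.character(utils::packageVersion("thoughtprobe")),
         stages = list())
  man$stages[[stage]] <- info
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

.need <- function(path, what) {
  assert_that(length(path) > 0 && all(file.exists(path)),
              sprintf("missing artifact: %s (%s); run the upstream stage first",
                      what, paste(utils::head(path, 1), collapse = "")))
}

# ---- stages ----------------------------------------------------------------

.st_simulate <- function(cfg, out) {
  sc <- .resolve_synth(cfg)
  cohort <- simulate_cohort(sc)
  dir.create(file.path(out, "recordings"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "ground_truth"), showWarnings = FALSE)
  all_reports <- list()
  for (key in names(cohort$task)) {
    b <- cohort$task[[key]]
    write_edf(b$recording, file.path(out, "recordings",
                                     paste0("task_", key, ".edf")))
    write_ground_truth(b$ground_truth,
                       file.path(out, "ground_truth",
                                 paste0("task_", key, ".json")))
    all_reports[[length(all_reports) + 1L]] <- cbind(b$reports, block = NA)
  }
  for (key in names(cohort$rest)) {
    b <- cohort$rest[[key]]
    write_edf(b$recording, file.path(out, "recordings",
                                     paste0("rest_", key, ".edf")))
    all_reports[[length(all_reports) + 1L]] <- b$report
  }
  write_reports(do.call(rbind, all_reports), file.path(out, "reports.csv"))
  .manifest_update(out, "simulate",
                   list(seed = sc$seed,
                        n_task = length(cohort$task),
                        n_rest = length(cohort$rest)))
  invisible(cohort)
}

.st_features <- function(cfg, out) {
  recs <- list.files(file.path(out, "recordings"), pattern = "\\.edf$",
                     full.names = TRUE)
  .need(file.path(out, "recordings"), "recordings directory")
  assert_that(length(recs) > 0, "missing artifact: recordings/*.edf; run simulate first")
  dir.create(file.path(out, "features"), showWarnings = FALSE)
  for (f in recs) {
    rec <- read_edf(f)
    epochs <- preprocess_recording(rec)
    mats <- lapply(epochs, epoch_spectral_matrix)
    write_features(mats, file.path(out, "features",
                                   sub("\\.edf$", ".csv", basename(f))))
  }
  .manifest_update(out, "features", list(n_recordings = length(recs)))
  invisible(length(recs))
}

# reconstruct labeled trials for all task (and optionally rest) sessions
.load_trials <- function(cfg, out, condition = "task") {
  feat_dir <- file.path(out, "features")
  .need(feat_dir, "features directory")
  files <- list.files(feat_dir, pattern = paste0("^", condition, "_.*\\.csv$"),
                      full.names = TRUE)
  assert_that(length(files) > 0,
              "missing artifact: features/*.csv; run the features stage first")
  reports <- read_reports(file.path(out, "reports.csv"))
  per_session <- list()
  for (f in files) {
    mats <- read_features(f)
    pid <- mats[[1]]$participant_id
    sid <- mats[[1]]$session_id
    if (condition == "task") {
      rep_s <- reports[reports$participant == pid & reports$session == sid &
                         reports$condition == "task", , drop = FALSE]
      tr <- assemble_trials(mats, rep_s, window_s = cfg$window_s)
    } else {
      block <- as.integer(sub("^.*_r([0-9]+)\\.csv$", "\\1", basename(f)))
      rep_s <- reports[reports$participant == pid & reports$session == sid &
                         reports$condition == "rest" &
                         reports$block == block, , drop = FALSE]
      tr <- label_rest(mats, rep_s)
    }
    per_session[[sub("\\.csv$", "", basename(f))]] <- tr
  }
  per_session
}

.st_label <- function(cfg, out) {
  per_session <- .load_trials(cfg, out, "task")
  all_tr <- do.call(bind_trials, per_session)
  lab_df <- cbind(all_tr$meta, as.data.frame(all_tr$labels))
  utils::write.csv(lab_df, file.path(out, "labels.csv"), row.names = FALSE)
  .manifest_update(out, "label", list(n_trials = nrow(lab_df)))
  invisible(all_tr)
}

.session_pairs_for <- function(per_session, dimension) {
  pairs <- lapply(per_session, session_condition_pairs, dimension = dimension)
  pairs[!vapply(pairs, is.null, logical(1))]
}

.st_cluster <- function(cfg, out) {
  per_session <- .load_trials(cfg, out, "task")
  dir.create(file.path(out, "cluster"), showWarnings = FALSE)
  adj <- electrode_adjacency(make_layout(), cfg$cluster$distance_threshold)
  excl <- list()
  for (d in thought_dimensions()) {
    pairs <- .session_pairs_for(per_session, d)
    excl[[d]] <- setdiff(names(per_session), names(pairs))
    if (length(pairs) < 2) next
    res <- cluster_permutation_test(
      lapply(pairs, function(p) p$upper$matrix),
      lapply(pairs, function(p) p$lower$matrix),
      adjacency = adj, n_perm = cfg$cluster$n_perm,
      cluster_alpha = cfg$cluster$cluster_alpha,
      seed = stage_seed(cfg$seed, paste0("cluster_", d)))
    write_cluster_result(res, file.path(out, "cluster", paste0(d, ".json")))
    utils::write.csv(res$t_map,
                     file.path(out, "cluster", paste0(d, "_tmap.csv")))
    utils::write.csv(cluster_mask(res) * 1L,
                     file.path(out, "cluster", paste0(d, "_mask.csv")))
  }
  .manifest_update(out, "cluster",
                   list(excluded_sessions = excl,
                        n_perm = cfg$cluster$n_perm))
  invisible(TRUE)
}

.st_lmm <- function(cfg, out) {
  .need(file.path(out, "cluster"), "cluster directory")
  per_session <- .load_trials(cfg, out, "task")
  reports <- read_reports(file.path(out, "reports.csv"))
  task_rep <- reports[reports$condition == "task", , drop = FALSE]
  rows <- list()
  for (d in thought_dimensions()) {
    mask_f <- file.path(out, "cluster", paste0(d, "_mask.csv"))
    if (!file.exists(mask_f)) next
    mask <- as.matrix(utils::read.csv(mask_f, row.names = 1)) > 0
    if (!any(mask)) next
    pairs <- .session_pairs_for(per_session, d)
    rt <- lmm_response_table(pairs, mask)
    fit1 <- fit_lmm_end(rt)
    top3 <- top_correlated_dimensions(task_rep, d)
    covs <- .end_mean_covariates(rt, task_rep, d, top3)
    fit2 <- tryCatch(fit_lmm_covariates(rt, covs),
                     error = function(e) NULL)
    est1 <- fit1$estimates[fit1$estimates$term == "endupper", ]
    rows[[d]] <- data.frame(
      dimension = d, estimate = est1$estimate, se = est1$se,
      lrt_p = fit1$lrt_p, singular = fit1$singular,
      covar_lrt_p = if (is.null(fit2)) NA else fit2$lrt_p,
      stringsAsFactors = FALSE)
  }
  empty <- data.frame(dimension = character(0), estimate = numeric(0),
                      se = numeric(0), lrt_p = numeric(0),
                      singular = logical(0), covar_lrt_p = numeric(0))
  utils::write.csv(if (length(rows)) do.call(rbind, rows) else empty,
                   file.path(out, "lmm.csv"), row.names = FALSE)
  .manifest_update(out, "lmm", list(dimensions = names(rows)))
  invisible(TRUE)
}

# session x end mean ratings of each participant's top-3 correlated
# dimensions, aligned with the response-table rows
.end_mean_covariates <- function(response_table, task_reports, dimension,
                                 top3) {
  out <- matrix(NA_real_, nrow(response_table), 3,
                dimnames = list(NULL, paste0("cov", 1:3)))
  for (i in seq_len(nrow(response_table))) {
    p <- response_table$participant[i]
    s <- response_table$session[i]
    end <- response_table$end[i]
    rs <- task_reports[task_reports$participant == p &
                         task_reports$session == s, , drop = FALSE]
    cls <- dichotomize(rs[[dimension]])
    sel <- rs[cls == end, , drop = FALSE]
    if (!nrow(sel)) sel <- rs
    dims3 <- top3[[p]]
    out[i, ] <- vapply(dims3, function(dd)
      mean(sel[[dd]], na.rm = TRUE), numeric(1))
  }
  as.data.frame(out)
}

.st_similarity <- function(cfg, out) {
  task_sessions <- .load_trials(cfg, out, "task")
  rest_sessions <- .load_trials(cfg, out, "rest")
  rest_labels <- do.call(rbind, lapply(rest_sessions, function(tr)
    cbind(tr$meta["participant"], as.data.frame(tr$labels))))
  excluded <- cohort_rest_exclusions(rest_labels)
  rows <- list()
  for (d in setdiff(thought_dimensions(), excluded)) {
    tp <- .session_pairs_for(task_sessions, d)
    rp <- .session_pairs_for(rest_sessions, d)
    if (length(tp) < 1 || length(rp) < 1) next
    sim <- task_rest_similarity(grand_difference_matrix(tp),
                                grand_difference_matrix(rp))
    rows[[d]] <- data.frame(dimension = d, r = sim$r, p = sim$p,
                            n_task_sessions = length(tp),
                            n_rest_blocks = length(rp))
  }
  empty <- data.frame(dimension = character(0), r = numeric(0),
                      p = numeric(0), n_task_sessions = integer(0),
                      n_rest_blocks = integer(0))
  utils::write.csv(if (length(rows)) do.call(rbind, rows) else empty,
                   file.path(out, "similarity.csv"), row.names = FALSE)
  .manifest_update(out, "similarity",
                   list(excluded_dimensions = as.list(excluded)))
  invisible(TRUE)
}

.st_classify <- function(cfg, out) {
  per_session <- .load_trials(cfg, out, "task")
  all_tr <- do.call(bind_trials, per_session)
  scfg <- do.call(scnn_config, cfg$scnn)
  dims <- cfg$classify$dimensions %||% thought_dimensions()
  rows <- list()
  for (d in dims) {
    res <- tryCatch(within_participant_cv(
      all_tr, d, config = scfg,
      n_iterations = cfg$classify$n_iterations,
      seed = stage_seed(cfg$seed, paste0("clf_", d)),
      min_class_trials = cfg$classify$min_class_trials),
      error = function(e) NULL)
    if (is.null(res)) next
    row <- data.frame(dimension = d, approach = "within_participant",
                      mcc_mean = res$mean["mcc"], mcc_sd = res$sd["mcc"],
                      auc_mean = res$mean["auc"], auc_sd = res$sd["auc"],
                      ba_mean = res$mean["ba"], ba_sd = res$sd["ba"],
                      n_participants = length(res$participants),
                      excluded = paste(res$excluded, collapse = ";"))
    rows[[paste0(d, "_within")]] <- row
    if (isTRUE(cfg$classify$loso)) {
      lr <- tryCatch(loso_transfer_cv(
        all_tr, d, config = scfg,
        n_iterations = cfg$classify$n_iterations,
        seed = stage_seed(cfg$seed, paste0("loso_", d)),
        min_class_trials = cfg$classify$min_class_trials),
        error = function(e) NULL)
      if (!is.null(lr)) {
        rows[[paste0(d, "_loso")]] <- data.frame(
          dimension = d, approach = "loso_transfer",
          mcc_mean = lr$mean["mcc"], mcc_sd = lr$sd["mcc"],
          auc_mean = lr$mean["auc"], auc_sd = lr$sd["auc"],
          ba_mean = lr$mean["ba"], ba_sd = lr$sd["ba"],
          n_participants = length(lr$participants),
          excluded = paste(lr$excluded, collapse = ";"))
      }
    }
  }
  assert_that(length(rows) > 0, "no dimension was classifiable")
  utils::write.csv(do.call(rbind, rows), file.path(out, "performance.csv"),
                   row.names = FALSE)
  .manifest_update(out, "classify", list(dimensions = dims))
  invisible(TRUE)
}

#' Render the run report
#'
#' Assembles a markdown summary from the run's artifact files: cluster
#' significance per dimension (with overlap against the planted ground
#' truth when sidecars are present), mixed-model estimates, task-rest
#' similarity, and the decoding-performance table. Sections whose artifacts
#' are missing are flagged, not fatal. Regeneration from the same artifacts
#' is byte-identical.
#'
#' @param run_dir run output directory.
#' @return path to `report.md`, invisibly.
#' @export
report <- function(run_dir) {
  lines <- c("# Ongoing-thought EEG pipeline report", "")
  clu_dir <- file.path(run_dir, "cluster")
  if (dir.exists(clu_dir)) {
    lines <- c(lines, "## Cluster-based permutation tests", "")
    for (f in list.files(clu_dir, pattern = "^[a-z_]+\\.json$",
                         full.names = TRUE)) {
      d <- sub("\\.json$", "", basename(f))
      res <- jsonlite::read_json(f, simplifyVector = TRUE)
      n_sig <- if (length(res$clusters)) sum(res$clusters$p < 0.05) else 0
      min_p <- if (length(res$clusters)) min(res$clusters$p) else NA
      ln <- sprintf("- **%s**: %d cluster(s), %d significant (min p = %s)",
                    d, NROW(res$clusters), n_sig,
                    ifelse(is.na(min_p), "-", format(min_p, digits = 3)))
      jac <- .planted_jaccard(run_dir, d)
      if (!is.na(jac)) {
        ln <- paste0(ln, sprintf("; Jaccard overlap with planted region = %.2f",
                                 jac))
      }
      lines <- c(lines, ln)
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "## Cluster-based permutation tests",
               "", "_missing: cluster stage not run_", "")
  }
  for (sec in list(c("lmm.csv", "Mixed-model controls"),
                   c("similarity.csv", "Task-rest similarity"),
                   c("performance.csv", "Decoding performance"))) {
    f <- file.path(run_dir, sec[1])
    lines <- c(lines, paste0("## ", sec[2]), "")
    if (file.exists(f)) {
      df <- utils::read.csv(f, stringsAsFactors = FALSE)
      lines <- c(lines, .md_table(df), "")
    } else {
      lines <- c(lines, sprintf("_missing: %s not found_", sec[1]), "")
    }
  }
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

.planted_jaccard <- function(run_dir, dimension) {
  mask_f <- file.path(run_dir, "cluster", paste0(dimension, "_mask.csv"))
  gt_dir <- file.path(run_dir, "ground_truth")
  if (!file.exists(mask_f) || !dir.exists(gt_dir)) return(NA_real_)
  gt_files <- list.files(gt_dir, full.names = TRUE)
  if (!length(gt_files)) return(NA_real_)
  gt <- read_ground_truth(gt_files[1])
  if (!dimension %in% names(gt$effect_masks)) return(NA_real_)
  found <- as.matrix(utils::read.csv(mask_f, row.names = 1)) > 0
  planted <- gt$effect_masks[[dimension]]
  u <- sum(found | planted)
  if (u == 0) return(NA_real_)
  sum(found & planted) / u
}

.md_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste0("| ", paste(colnames(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Run pipeline stages from a configuration
#'
#' Commands: `simulate`, `features`, `label`, `cluster-test`, `lmm`,
#' `similarity`, `classify`, `report`, or `all`. Each stage writes its
#' artifacts under `out_dir` and records itself in `manifest.json`; the
#' resolved configuration is written next to the outputs. Errors (including
#' missing upstream artifacts) produce a diagnostic and a nonzero status.
#'
#' @param command stage name (see above).
#' @param config a `run_config`, or a path to a JSON config file.
#' @param out_dir output directory (created if absent).
#' @return integer status, 0 on success, invisibly.
#' @export
cli_run <- function(command, config = run_config(), out_dir = "run") {
  cmds <- c("simulate", "features", "label", "cluster-test", "lmm",
            "similarity", "classify", "report", "all")
  if (!command %in% cmds) {
    message(sprintf("unknown command '%s' (expected one of: %s)",
                    command, paste(cmds, collapse = ", ")))
    return(invisible(1L))
  }
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", force = TRUE),
             file.path(out_dir, "run_config.json"))
  stages <- if (command == "all") {
    c("simulate", "features", "label", "cluster-test", "lmm",
      "similarity", "classify", "report")
  } else command
  for (st in stages) {
    ok <- tryCatch({
      switch(st,
             "simulate" = .st_simulate(cfg, out_dir),
             "features" = .st_features(cfg, out_dir),
             "label" = .st_label(cfg, out_dir),
             "cluster-test" = .st_cluster(cfg, out_dir),
             "lmm" = .st_lmm(cfg, out_dir),
             "similarity" = .st_similarity(cfg, out_dir),
             "classify" = .st_classify(cfg, out_dir),
             "report" = report(out_dir))
      TRUE
    }, error = function(e) {
      message(sprintf("stage '%s' failed: %s", st, conditionMessage(e)))
      FALSE
    })
    if (!ok) return(invisible(1L))
  }
  invisible(0L)
}
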