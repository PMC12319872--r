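# Linear mixed-model control analyses.
#
# The cluster-based permutation test treats session-level matrices as
# independent; these models verify the upper-vs-lower effect while
# accounting for participant-level variance (random intercepts of
# participant and session nested within participant) and, in a second
# model, for the ratings of the three dimensions most correlated with the
# dimension of interest.

#' Build the LMM response table from session pairs
#'
#' The response is the session-level mean of the periodic features inside a
#' significant cluster, one row per session x end.
#'
#' @param session_pairs named list of session pairs (names "pid_sid"), as
#'   from [session_condition_pairs()]; `NULL` entries (excluded sessions)
#'   are dropped.
#' @param mask logical electrodes x frequencies matrix (e.g.
#'   [cluster_mask()]).
#' @return data.frame with columns `response`, `end`, `participant`,
#'   `session`.
#' @export
lmm_response_table <- function(session_pairs, mask) {
  session_pairs <- Filter(Negate(is.null), session_pairs)
  assert_that(length(session_pairs) >= 1, "no included session pairs")
  assert_that(any(mask), "mask selects no cells")
  rows <- lapply(names(session_pairs), function(key) {
    p <- session_pairs[[key]]
    do.call(rbind, lapply(c("upper", "lower"), function(end) data.frame(
      response = mean(p[[end]]$matrix$periodic[mask]),
      end = end,
      participant = p[[end]]$matrix$participant_id,
      session = p[[end]]$matrix$session_id,
      stringsAsFactors = FALSE)))
  })
  do.call(rbind, rows)
}

#' Mixed model for the dimension-end effect
#'
#' Fits `response ~ end + (1 | participant) + (1 | participant:session)` by
#' maximum likelihood and tests the end effect with a likelihood-ratio test
#' against the model without it. Singular fits are flagged, not raised.
#'
#' @param response_table data.frame from [lmm_response_table()] (columns
#'   `response`, `end`, `participant`, `session`).
#' @return an `lmm_result`: `estimates` (fixed effects with SEs),
#'   `varcomp` (variance components), `lrt_p`, `singular`, `model`.
#' @export
fit_lmm_end <- function(response_table) {
  rt <- response_table
  rt$end <- factor(rt$end, levels = c("lower", "upper"))
  full <- suppressMessages(lme4::lmer(
    response ~ end + (1 | participant) + (1 | participant:session),
    data = rt, REML = FALSE,
    control = .lmm_control()))
  null <- suppressMessages(lme4::lmer(
    response ~ 1 + (1 | participant) + (1 | participant:session),
    data = rt, REML = FALSE,
    control = .lmm_control()))
  .lmm_result(full, null, "endupper")
}

#' Mixed model controlling for correlated-dimension ratings
#'
#' Fits `response ~ end + covariates + (1 | participant)`, where the
#' covariates are the session x end mean ratings of the three dimensions
#' most correlated with the dimension of interest (optionally plus age and
#' sex). Collinear covariates are flagged and the fit proceeds on the
#' reduced-rank design with a warning.
#'
#' @param response_table as in [fit_lmm_end()].
#' @param covariate_ratings data.frame of covariate columns aligned
#'   row-for-row with `response_table`.
#' @return an `lmm_result` with an added `collinear` flag.
#' @export
fit_lmm_covariates <- function(response_table, covariate_ratings) {
  rt <- response_table
  rt$end <- factor(rt$end, levels = c("lower", "upper"))
  stopifnot(nrow(covariate_ratings) == nrow(rt))
  covs <- as.data.frame(covariate_ratings)
  X <- cbind(end = as.numeric(rt$end == "upper"),
             as.matrix(data.matrix(covs)))
  collinear <- qr(cbind(1, X))$rank < (ncol(X) + 1)
  if (collinear) {
    warning("collinear covariates detected; fit proceeds on reduced rank")
  }
  dat <- cbind(rt, covs)
  fml <- stats::as.formula(paste(
    "response ~ end +", paste(colnames(covs), collapse = " + "),
    "+ (1 | participant)"))
  fml0 <- stats::as.formula(paste(
    "response ~", paste(colnames(covs), collapse = " + "),
    "+ (1 | participant)"))
  full <- suppressMessages(lme4::lmer(
    fml, data = dat, REML = FALSE,
    control = .lmm_control()))
  null <- suppressMessages(lme4::lmer(
    fml0, data = dat, REML = FALSE,
    control = .lmm_control()))
  out <- .lmm_result(full, null, "endupper")
  out$collinear <- collinear
  out
}

.lmm_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.nlev.gtr.1 = "ignore",
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore")
}

.lmm_result <- function(full, null, effect_name) {
  cf <- lme4::fixef(full)
  se <- sqrt(diag(as.matrix(stats::vcov(full))))
  lrt <- as.numeric(2 * (stats::logLik(full) - stats::logLik(null)))
  vc <- as.data.frame(lme4::VarCorr(full))
  structure(list(
    estimates = data.frame(term = names(cf), estimate = as.numeric(cf),
                           se = se, stringsAsFactors = FALSE),
    varcomp = vc[, c("grp", "vcov")],
    lrt_stat = max(lrt, 0),
    lrt_p = stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
    singular = lme4::isSingular(full),
    effect = effect_name,
    model = full
  ), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  est <- x$estimates[x$estimates$term == x$effect, ]
  cat(sprintf("<lmm_result> end effect = %.4f (SE %.4f), LRT p = %.4g%s\n",
              est$estimate, est$se, x$lrt_p,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Wald 95% confidence interval for the end effect
#' @param result an `lmm_result`.
#' @return numeric `c(lower, upper)`.
#' @export
lmm_end_ci <- function(result) {
  est <- result$estimates[result$estimates$term == result$effect, ]
  est$estimate + c(-1, 1) * stats::qnorm(0.975) * est$se
}
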