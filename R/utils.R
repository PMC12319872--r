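# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(code)
}

#' Derive a reproducible per-stage seed from a root seed
#'
#' Combines the root seed with a polynomial hash of the stage name so that
#' pipeline stages can be rerun independently but reproducibly.
#'
#' @param root_seed integer root seed for the whole run.
#' @param stage character stage name, e.g. `"simulate"`.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(root_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647
  h <- as.double(root_seed) %% m
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  as.integer(h)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
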