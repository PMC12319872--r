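#' Thought-dimension identifiers
#'
#' The seven probed dimensions of ongoing thought, in the order they are
#' rated at each probe: task-relatedness (off-task), freely moving thought,
#' sticky thought (difficulty disengaging), goal-directed thought,
#' attentional focus (internal vs. external), self-oriented and
#' other-oriented content.
#'
#' @return character vector of length 7.
#' @export
thought_dimensions <- function() {
  c("off_task", "freely_moving", "sticky", "goal_directed",
    "internal", "self", "other")
}

# 32-channel 10-20 montage template. Positions are scalp-projected 2-D
# coordinates on a unit-circle head (x toward the right ear, y toward the
# nasion); approximate standard topographic-map locations.
.layout_table <- function() {
  tab <- rbind(
    c("Fp1", -0.31,  0.95), c("AF3", -0.22,  0.81), c("F7",  -0.81,  0.59),
    c("F3",  -0.40,  0.52), c("FC1", -0.20,  0.25), c("FC5", -0.63,  0.28),
    c("T7",  -1.00,  0.00), c("C3",  -0.50,  0.00), c("CP1", -0.20, -0.25),
    c("CP5", -0.63, -0.28), c("P7",  -0.81, -0.59), c("P3",  -0.40, -0.52),
    c("Pz",   0.00, -0.50), c("PO3", -0.22, -0.81), c("O1",  -0.31, -0.95),
    c("Oz",   0.00, -1.00), c("O2",   0.31, -0.95), c("PO4",  0.22, -0.81),
    c("P4",   0.40, -0.52), c("P8",   0.81, -0.59), c("CP6",  0.63, -0.28),
    c("CP2",  0.20, -0.25), c("C4",   0.50,  0.00), c("T8",   1.00,  0.00),
    c("FC6",  0.63,  0.28), c("FC2",  0.20,  0.25), c("F4",   0.40,  0.52),
    c("F8",   0.81,  0.59), c("AF4",  0.22,  0.81), c("Fp2",  0.31,  0.95),
    c("Fz",   0.00,  0.50), c("Cz",   0.00,  0.00)
  )
  labels <- tab[, 1]
  pos <- matrix(as.numeric(tab[, 2:3]), ncol = 2,
                dimnames = list(labels, c("x", "y")))
  # shrink slightly so even temporal/occipital sites sit inside the circle
  list(labels = labels, positions = pos * 0.98)
}

#' Standard 32-channel 10-20 electrode layout
#'
#' Returns the packaged montage template: 32 electrode labels with
#' deterministic 2-D scalp-projected positions on a unit-circle head.
#'
#' @return an object of class `channel_layout` with elements `labels`
#'   (character, length 32) and `positions` (32 x 2 numeric matrix,
#'   rownames = labels).
#' @examples
#' lay <- make_layout()
#' stopifnot(all(c("Fz", "Cz", "Pz", "Oz") %in% lay$labels))
#' @export
make_layout <- function() {
  lay <- .layout_table()
  structure(lay, class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout> ", length(x$labels), " electrodes (10-20 montage)\n",
      sep = "")
  invisible(x)
}

#' Pairwise electrode distances for a layout
#' @noRd
layout_distances <- function(layout) {
  as.matrix(stats::dist(layout$positions))
}
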