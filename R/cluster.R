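# Dependent-samples cluster-based permutation test over the
# electrode x frequency grid.
#
# Cells are adjacent if they share a frequency bin and their electrodes are
# layout neighbors, or share an electrode and sit in 1-Hz-adjacent bins
# (no diagonal adjacency). The cluster statistic is the maxsum (cluster
# mass); the null is the permutation distribution of the maximum absolute
# mass under within-pair sign flips.

#' Electrode adjacency from layout distances
#'
#' Electrodes are neighbors iff their 2-D layout distance is below
#' `distance_threshold`. The default threshold gives a mean degree of about
#' 6 on the packaged 32-channel montage.
#'
#' @param layout a `channel_layout`.
#' @param distance_threshold neighbor distance cutoff (unit-circle head
#'   coordinates).
#' @return an `adjacency` object: logical 32 x 32 matrix `electrodes`
#'   (symmetric, empty diagonal) plus the threshold.
#' @export
electrode_adjacency <- function(layout, distance_threshold = 0.55) {
  assert_that(distance_threshold > 0, "threshold must be positive")
  d <- layout_distances(layout)
  adj <- d < distance_threshold
  diag(adj) <- FALSE
  if (any(rowSums(adj) == 0)) {
    warning("distance_threshold leaves isolated electrodes")
  }
  structure(list(electrodes = adj, threshold = distance_threshold,
                 labels = layout$labels),
            class = "adjacency")
}

# Neighbor list over the flattened electrode x frequency grid
# (cell index = electrode + n_el * (bin - 1)), computed once per test.
.cell_neighbors <- function(adjacency, n_freq) {
  n_el <- nrow(adjacency$electrodes)
  el_nb <- lapply(seq_len(n_el), function(e) which(adjacency$electrodes[e, ]))
  nbrs <- vector("list", n_el * n_freq)
  for (b in seq_len(n_freq)) {
    base <- n_el * (b - 1)
    for (e in seq_len(n_el)) {
      nb <- el_nb[[e]] + base
      if (b > 1) nb <- c(nb, e + base - n_el)
      if (b < n_freq) nb <- c(nb, e + base + n_el)
      nbrs[[e + base]] <- nb
    }
  }
  nbrs
}

#' Paired t-statistic map
#'
#' Per electrode x frequency cell, the dependent-samples t statistic of the
#' session-level upper-minus-lower differences: `t = mean(d) /
#' (sd(d)/sqrt(n))`, df = n-1. Cells whose differences are identically zero
#' get t = 0.
#'
#' @param upper_matrices,lower_matrices session-aligned lists of
#'   `spectral_matrix` (same length n >= 2).
#' @return numeric matrix of t values (electrodes x frequencies).
#' @export
paired_t_map <- function(upper_matrices, lower_matrices) {
  n <- length(upper_matrices)
  assert_that(n == length(lower_matrices), "paired lists must align")
  assert_that(n >= 2, "paired t needs at least 2 session pairs")
  dims <- dim(upper_matrices[[1]]$periodic)
  D <- t(vapply(seq_len(n), function(i)
    as.vector(upper_matrices[[i]]$periodic - lower_matrices[[i]]$periodic),
    numeric(prod(dims))))
  .t_from_diffs(D, dims, dimnames(upper_matrices[[1]]$periodic))
}

.t_from_diffs <- function(D, dims, dn = NULL) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tt <- ifelse(v == 0, ifelse(m == 0, 0, sign(m) * Inf),
               m / sqrt(v / n))
  out <- matrix(tt, dims[1], dims[2])
  if (!is.null(dn)) dimnames(out) <- dn
  out
}

#' Find suprathreshold clusters in a t map
#'
#' Connected components of `{|t| >= threshold_t}` under the combined
#' electrode/frequency adjacency, split by sign. Cluster mass is the sum of
#' member t values.
#'
#' @param t_map electrodes x frequencies matrix of t values.
#' @param threshold_t positive cluster-forming threshold.
#' @param adjacency an `adjacency` from [electrode_adjacency()].
#' @return list of clusters, each `list(cells = integer indices into the
#'   flattened map, mass, sign)`, ordered by decreasing |mass|.
#' @export
find_clusters <- function(t_map, threshold_t, adjacency) {
  assert_that(threshold_t > 0, "threshold_t must be positive")
  nbrs <- .cell_neighbors(adjacency, ncol(t_map))
  .find_clusters_impl(as.vector(t_map), threshold_t, nbrs)
}

# BFS over suprathreshold cells of one sign at a time
.find_clusters_impl <- function(tv, thr, nbrs) {
  clusters <- list()
  for (sgn in c(1, -1)) {
    supra <- sgn * tv >= thr
    todo <- which(supra)
    visited <- logical(length(tv))
    for (s in todo) {
      if (visited[s]) next
      comp <- integer(0)
      stack <- s
      visited[s] <- TRUE
      while (length(stack)) {
        cur <- stack[length(stack)]
        stack <- stack[-length(stack)]
        comp <- c(comp, cur)
        for (nb in nbrs[[cur]]) {
          if (supra[nb] && !visited[nb]) {
            visited[nb] <- TRUE
            stack <- c(stack, nb)
          }
        }
      }
      clusters[[length(clusters) + 1L]] <-
        list(cells = sort(comp), mass = sum(tv[comp]), sign = sgn)
    }
  }
  if (length(clusters)) {
    clusters <- clusters[order(-vapply(clusters, function(cl)
      abs(cl$mass), numeric(1)))]
  }
  clusters
}

# max |cluster mass| for one t vector (fast path used in the permutation
# loop; 0 when nothing is suprathreshold)
.max_cluster_mass <- function(tv, thr, nbrs) {
  cl <- .find_clusters_impl(tv, thr, nbrs)
  if (!length(cl)) 0 else abs(cl[[1]]$mass)
}

#' Dependent-samples cluster-based permutation test
#'
#' Tests upper vs. lower session-level spectral matrices. Observed clusters
#' are formed at the two-tailed t threshold `qt(1 - cluster_alpha/2, n-1)`;
#' the null distribution is the maximum absolute cluster mass under random
#' within-pair sign flips; each observed cluster's Monte-Carlo p is
#' `(r + 1) / (n_perm + 1)` where `r` counts null maxima at or above its
#' |mass|.
#'
#' @param upper,lower session-aligned lists of `spectral_matrix`.
#' @param adjacency an `adjacency`; default from the packaged layout.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param cluster_alpha two-tailed alpha of the cluster-forming threshold.
#' @param seed RNG seed (recorded in the result).
#' @return a `cluster_result`: `t_map`, `clusters` (with `cells`, `mass`,
#'   `sign`, `p`), `threshold_t`, `null_max`, `n_perm`, `seed`.
#' @export
cluster_permutation_test <- function(upper, lower, adjacency = NULL,
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     seed = 1L) {
  n <- length(upper)
  assert_that(n >= 2, "need at least 2 session pairs")
  assert_that(n_perm >= 100, "n_perm must be at least 100")
  if (is.null(adjacency)) adjacency <- electrode_adjacency(make_layout())
  dims <- dim(upper[[1]]$periodic)
  D <- t(vapply(seq_len(n), function(i)
    as.vector(upper[[i]]$periodic - lower[[i]]$periodic),
    numeric(prod(dims))))
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  nbrs <- .cell_neighbors(adjacency, dims[2])
  t_obs <- .t_from_diffs(D, dims, dimnames(upper[[1]]$periodic))
  clusters <- .find_clusters_impl(as.vector(t_obs), thr, nbrs)

  sq <- colSums(D^2)
  null_max <- with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    S <- flips %*% D
    m <- S / n
    v <- sweep(-n * m^2, 2, sq, `+`) / (n - 1)
    v[v < 0] <- 0
    Tm <- ifelse(v == 0, ifelse(m == 0, 0, sign(m) * Inf), m / sqrt(v / n))
    vapply(seq_len(n_perm), function(i)
      .max_cluster_mass(Tm[i, ], thr, nbrs), numeric(1))
  })
  for (i in seq_along(clusters)) {
    r <- sum(null_max >= abs(clusters[[i]]$mass))
    clusters[[i]]$p <- (r + 1) / (n_perm + 1)
  }
  structure(list(t_map = t_obs, clusters = clusters, threshold_t = thr,
                 null_max = null_max, n_perm = n_perm, seed = seed,
                 n_pairs = n, labels = adjacency$labels),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d pairs, %d permutations, threshold |t| >= %.3f\n",
              x$n_pairs, x$n_perm, x$threshold_t))
  if (!length(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  cluster %d: %d cells, mass %.2f (%s), p = %.4f\n",
                  i, length(cl$cells), cl$mass,
                  if (cl$sign > 0) "positive" else "negative", cl$p))
    }
  }
  invisible(x)
}

#' Significance mask of a cluster result
#'
#' @param result a `cluster_result`.
#' @param alpha significance level.
#' @return logical electrodes x frequencies matrix marking cells belonging
#'   to any cluster with p < alpha.
#' @export
cluster_mask <- function(result, alpha = 0.05) {
  m <- matrix(FALSE, nrow(result$t_map), ncol(result$t_map),
              dimnames = dimnames(result$t_map))
  for (cl in result$clusters) if (cl$p < alpha) m[cl$cells] <- TRUE
  m
}

#' Mean upper-minus-lower difference matrix
#'
#' Grand mean across included session pairs of the (upper - lower)
#' session-level matrices, used for the task-rest comparison.
#'
#' @param session_pairs list of pairs as returned by
#'   [session_condition_pairs()] (non-NULL entries).
#' @return a `spectral_matrix` of mean differences.
#' @export
grand_difference_matrix <- function(session_pairs) {
  session_pairs <- Filter(Negate(is.null), session_pairs)
  assert_that(length(session_pairs) >= 1, "no included session pairs")
  diffs <- lapply(session_pairs, function(p) {
    m <- p$upper$matrix
    m$periodic <- p$upper$matrix$periodic - p$lower$matrix$periodic
    m
  })
  out <- session_mean_matrix(diffs)
  out$end <- "difference"
  out
}

#' Task-rest spectral similarity
#'
#' Pearson correlation over all paired electrode x frequency entries (864
#' for the 32 x 27 grid), with a two-sided p from the t distribution with
#' `n_cells - 2` df.
#'
#' @param task_matrix,rest_matrix `spectral_matrix` objects on the same grid.
#' @return list with `r`, `p`, `n`.
#' @export
task_rest_similarity <- function(task_matrix, rest_matrix) {
  a <- as.vector(task_matrix$periodic)
  b <- as.vector(rest_matrix$periodic)
  assert_that(length(a) == length(b), "grid mismatch")
  assert_that(stats::sd(a) > 0 && stats::sd(b) > 0,
              "similarity undefined for zero-variance matrices")
  n <- length(a)
  r <- stats::cor(a, b)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}
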