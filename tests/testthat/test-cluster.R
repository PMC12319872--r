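test_that("paired t map matches the textbook formula", {
  set.seed(13)
  up <- lapply(1:30, function(i) rand_spectral())
  lo <- lapply(1:30, function(i) rand_spectral())
  tm <- paired_t_map(up, lo)
  expect_equal(dim(tm), c(32, 27))
  # direct formula oracle
  D <- sapply(1:30, function(i) as.vector(up[[i]]$periodic - lo[[i]]$periodic))
  want <- apply(D, 1, function(d) mean(d) / (sd(d) / sqrt(30)))
  expect_lt(max(abs(as.vector(tm) - want)), 1e-12)
  # identical lists -> all-zero map
  expect_true(all(paired_t_map(up, up) == 0))
  expect_error(paired_t_map(up[1], lo[1]), "at least 2")
})

test_that("cluster finding equals an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  lay <- make_layout()
  adj <- electrode_adjacency(lay)
  # full cell graph for the oracle
  nbrs <- thoughtprobe:::.cell_neighbors(adj, 27)
  edges <- do.call(rbind, lapply(seq_along(nbrs), function(i) {
    nb <- nbrs[[i]][nbrs[[i]] > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  oracle_clusters <- function(tv, thr) {
    out <- list()
    for (sgn in c(1, -1)) {
      supra <- which(sgn * tv >= thr)
      if (!length(supra)) next
      keep <- edges[edges[, 1] %in% supra & edges[, 2] %in% supra, ,
                    drop = FALSE]
      g <- igraph::graph_from_data_frame(
        as.data.frame(keep), directed = FALSE,
        vertices = data.frame(name = supra))
      comp <- igraph::components(g)$membership
      for (k in unique(comp)) {
        cells <- sort(as.integer(names(comp)[comp == k]))
        out[[length(out) + 1]] <- list(cells = cells, mass = sum(tv[cells]))
      }
    }
    out[order(-vapply(out, function(cl) abs(cl$mass), numeric(1)))]
  }
  set.seed(14)
  for (i in 1:10) {
    tv <- rnorm(864, sd = 1.5)
    got <- thoughtprobe:::.find_clusters_impl(tv, 2.0, nbrs)
    want <- oracle_clusters(tv, 2.0)
    expect_equal(lapply(got, function(cl) as.integer(cl$cells)),
                 lapply(want, function(cl) as.integer(cl$cells)))
    expect_equal(vapply(got, `[[`, numeric(1), "mass"),
                 vapply(want, `[[`, numeric(1), "mass"), tolerance = 1e-12)
  }
})

test_that("degenerate cluster configurations behave as specified", {
  lay <- make_layout()
  adj <- electrode_adjacency(lay)
  tm <- matrix(0, 32, 27)
  tm[5, 10] <- 3.2
  cl <- find_clusters(tm, 2.5, adj)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$cells, 5L + 32L * 9L)
  expect_equal(cl[[1]]$mass, 3.2)
  # two suprathreshold cells at non-neighboring electrodes, same bin
  far <- which(!adj$electrodes[5, ])
  far <- far[far != 5][1]
  tm[far, 10] <- 3.0
  expect_length(find_clusters(tm, 2.5, adj), 2)
  expect_length(find_clusters(matrix(0, 32, 27), 2.5, adj), 0)
})

test_that("permutation test p-values are granular and relabel-symmetric", {
  set.seed(15)
  up <- lapply(1:3, function(i) rand_spectral(shift = 0.3))
  lo <- lapply(1:3, function(i) rand_spectral())
  res <- cluster_permutation_test(up, lo, n_perm = 100, seed = 3)
  if (length(res$clusters)) {
    p <- vapply(res$clusters, `[[`, numeric(1), "p")
    expect_true(all(abs(p * 101 - round(p * 101)) < 1e-9))
    expect_true(all(p >= 1 / 101))
  }
  # swapping upper and lower flips cluster signs, keeps p-values
  res2 <- cluster_permutation_test(lo, up, n_perm = 100, seed = 3)
  expect_equal(vapply(res$clusters, `[[`, numeric(1), "p"),
               vapply(res2$clusters, `[[`, numeric(1), "p"))
  expect_equal(vapply(res$clusters, `[[`, numeric(1), "mass"),
               -vapply(res2$clusters, `[[`, numeric(1), "mass"))
})

test_that("grand difference and task-rest similarity behave like Pearson", {
  set.seed(16)
  mk_pair <- function(u, l) list(
    upper = list(matrix = u, n_trials = 5),
    lower = list(matrix = l, n_trials = 5))
  a <- rand_spectral(); b <- rand_spectral()
  gd <- grand_difference_matrix(list(mk_pair(a, b)))
  expect_equal(gd$periodic, a$periodic - b$periodic)
  # antisymmetric pair set cancels
  gd0 <- grand_difference_matrix(list(mk_pair(a, b), mk_pair(b, a)))
  expect_lt(max(abs(gd0$periodic)), 1e-12)
  # oracle mean of differences
  c_ <- rand_spectral(); d_ <- rand_spectral()
  gd2 <- grand_difference_matrix(list(mk_pair(a, b), mk_pair(c_, d_)))
  expect_equal(gd2$periodic,
               (a$periodic - b$periodic + c_$periodic - d_$periodic) / 2,
               tolerance = 1e-12)

  expect_equal(task_rest_similarity(a, a)$r, 1)
  neg <- a; neg$periodic <- -a$periodic
  expect_equal(task_rest_similarity(a, neg)$r, -1)
  sim <- task_rest_similarity(a, b)
  ct <- cor.test(as.vector(a$periodic), as.vector(b$periodic))
  expect_equal(sim$r, unname(ct$estimate))
  expect_equal(sim$p, ct$p.value, tolerance = 1e-12)
  # independent random matrices are near-uncorrelated in >= 95% of draws
  hits <- sum(replicate(40, abs(task_rest_similarity(rand_spectral(),
                                                     rand_spectral())$r) < 0.1))
  expect_gte(hits, 38)
  flat <- a; flat$periodic[] <- 1
  expect_error(task_rest_similarity(a, flat), "zero-variance")
})
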