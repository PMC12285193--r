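# Clustering, spanning-tree geometry, path finding, interpolation,
# pseudotime assignment, pattern reconstruction, peak calling.

test_that("well-separated blobs are never merged and resolve to two clusters", {
  set.seed(1)
  z <- rbind(matrix(rnorm(500), 250, 2),
             matrix(rnorm(500, mean = 40), 250, 2))  # 20 sigma apart
  truth <- rep(1:2, each = 250)
  # kNN graph disconnectedness oracle: no cross-blob pair within k distances
  d_cross <- sqrt(min(outer(rowSums(z[1:250, ]^2), rowSums(z[251:500, ]^2), "+")
                      - 2 * tcrossprod(z[1:250, ], z[251:500, ])))
  d_within_max <- max(apply(as.matrix(dist(z[1:250, ])), 1,
                            function(r) sort(r)[16]))
  expect_gt(d_cross, d_within_max)  # graph cannot connect the blobs
  lab <- cluster_latent(z, n_neighbors = 15, resolution = 0.05, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_true(all(table(lab, truth) %in% c(0, 250)))
  # default resolution may subdivide blobs but must never merge them
  lab2 <- cluster_latent(z, n_neighbors = 15, resolution = 0.7, seed = 1)
  expect_true(all(apply(table(lab2, truth) > 0, 1, sum) == 1))
  # determinism and contiguity of ids
  expect_identical(lab2, cluster_latent(z, 15, 0.7, seed = 1))
  expect_identical(sort(unique(lab2)), seq(0L, max(lab2)))
  expect_warning(cluster_latent(matrix(1, 50, 2), 5, 0.7, 1), "single cluster")
})

test_that("MST of collinear centroids is the chain, with K-1 edges", {
  emb <- list(v = rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0), c(2, 0), c(2, 0)),
              z = matrix(0, 6, 2))
  g <- build_cluster_graph(emb, c(0, 0, 1, 1, 2, 2))
  expect_equal(nrow(g$mst_edges), 2)
  expect_equal(sum(g$mst_edges$weight), 2)
  pairs <- apply(g$mst_edges[, 1:2], 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(pairs, c("0-1", "1-2"))
})

test_that("MST weight equals the brute-force optimum over all spanning trees", {
  # Cayley: 6^{6-2} = 1296 labelled trees via Pruefer sequences
  set.seed(33)
  n <- 6
  v <- matrix(rnorm(2 * n), n, 2)
  labels <- rep(0:(n - 1), each = 3)
  emb <- list(v = v[labels + 1, ] + matrix(rnorm(6 * n, sd = 1e-9), 3 * n, 2),
              z = matrix(0, 3 * n, 2))
  g <- build_cluster_graph(emb, labels)
  D <- as.matrix(dist(g$centroids_v))
  prufer_tree <- function(seq) {
    # decode a Pruefer sequence into an edge list
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 0L
    for (i in seq_along(seq)) {
      leaf <- which(degree == 1L)[1]
      edges[i, ] <- c(leaf, seq[i])
      degree[leaf] <- 0L
      degree[seq[i]] <- degree[seq[i]] - 1L
    }
    rest <- which(degree == 1L)
    edges[n - 1, ] <- rest
    edges
  }
  combos <- expand.grid(rep(list(seq_len(n)), n - 2))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    ed <- prufer_tree(as.integer(combos[r, ]))
    best <- min(best, sum(D[ed]))
  }
  expect_equal(sum(g$mst_edges$weight), best, tolerance = 1e-9)
  expect_equal(nrow(g$mst_edges), n - 1)
  expect_true(igraph::is_connected(g$tree))
})

make_line_graph <- function(centroids) {
  n <- nrow(centroids)
  labels <- seq_len(n) - 1L
  emb <- list(v = centroids, z = centroids)
  # one cell per cluster is impossible (centroid of one point is itself)
  build_cluster_graph(emb, labels)
}

test_that("path endpoints are the marker argmax clusters and the tree path is exact", {
  set.seed(40)
  cent <- cbind(seq(0, 3), 0)
  g <- make_line_graph(cent)
  # counts: gene A high in cluster 0, gene B high in cluster 3
  x <- matrix(rpois(4 * 4, 2), 4, 4)
  x[1, 1] <- 60; x[4, 2] <- 60
  cm <- count_matrix(x, gene_ids = c("A", "B", "C", "D"))
  p <- find_path(g, cm, start_markers = "A", end_markers = "B")
  expect_equal(p, 0:3)
  expect_error(find_path(g, cm, start_markers = "A", end_markers = "A"),
               "same cluster")
  expect_error(find_path(g, cm, start_markers = "ZZZ", end_markers = "B"),
               "absent")
})

test_that("tree path matches a breadth-first search oracle on a random tree", {
  set.seed(41)
  for (rep in 1:3) {
    cent <- matrix(rnorm(14), 7, 2)
    g <- make_line_graph(cent)
    from <- 0L; to <- 6L
    p <- find_path(g, start_cluster = from, end_cluster = to)
    # BFS oracle on the MST edge list
    adj <- lapply(0:6, function(i) {
      e <- g$mst_edges
      c(e$to[e$from == i], e$from[e$to == i])
    })
    queue <- list(from); parent <- rep(NA_integer_, 7); seen <- from
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (nb in adj[[cur + 1]]) {
        if (!(nb %in% seen)) {
          seen <- c(seen, nb); parent[nb + 1] <- cur; queue <- c(queue, nb)
        }
      }
    }
    oracle <- to
    while (oracle[1] != from) oracle <- c(parent[oracle[1] + 1], oracle)
    expect_equal(p, oracle)
  }
})

test_that("interpolation produces the documented times", {
  g <- make_line_graph(rbind(c(0, 0), c(1, 0)))
  p <- interpolate_path(g, c(0, 1), spacing = 0.25)
  expect_equal(p$times, c(0, 0.25, 0.5, 0.75, 1))
  # right-angle path: total time is the polyline length
  g2 <- make_line_graph(rbind(c(0, 0), c(1, 0), c(1, 1)))
  p2 <- interpolate_path(g2, c(0, 1, 2), spacing = 0.3)
  expect_equal(max(p2$times), 2)
  expect_equal(p2$times[1], 0)
  expect_true(all(diff(p2$times) > 0))
  # total time is spacing-invariant
  p3 <- interpolate_path(g2, c(0, 1, 2), spacing = 0.017)
  expect_equal(max(p3$times), 2)
  expect_error(interpolate_path(g2, c(0, 1, 2), spacing = 0), "spacing")
})

test_that("pseudotime assignment: vertices, symmetry, and the projection oracle", {
  g <- make_line_graph(rbind(c(0, 0), c(4, 0)))
  path <- interpolate_path(g, c(0, 1), spacing = 0.05)
  emb <- list(v = rbind(c(2, 0), c(1, 1), c(1, -1), c(0, 0)),
              z = matrix(0, 4, 2), cell_ids = paste0("c", 1:4))
  res <- assign_time(structure(emb, class = "decipher_embedding"), path)
  expect_equal(res$time[1], 2)       # exactly on a vertex of the polyline
  expect_equal(res$distance[1], 0)
  expect_equal(res$time[2], res$time[3])      # mirror symmetry
  expect_equal(res$distance[2], res$distance[3])
  expect_equal(res$time[4], 0)
  # continuous projection oracle: for points near a segment the discretized
  # time is within one spacing step of the exact orthogonal projection
  set.seed(42)
  pts <- cbind(runif(50, 0, 4), runif(50, -1, 1))
  emb2 <- structure(list(v = pts, z = pts, cell_ids = paste0("p", 1:50)),
                    class = "decipher_embedding")
  res2 <- assign_time(emb2, path)
  exact <- pmin(pmax(pts[, 1], 0), 4)  # projection onto the segment
  expect_lte(max(abs(res2$time - exact)), 0.05 + 1e-9)
  expect_error(assign_time(emb2, list(a = path), rep("b", 50)), "no trajectory")
})

test_that("reconstructed patterns equal decode and keep band ordering", {
  model <- tiny_model(G = 12)
  g <- make_line_graph(rbind(c(-1, 0), c(1, 0.5)))
  path <- interpolate_path(g, c(0, 1), spacing = 0.1)
  genes <- model$gene_ids[c(2, 5)]
  ps <- reconstruct_gene_patterns(model, path, genes, n_samples = 40,
                                  library_size = 10, seed = 2)
  dec <- decipher_decode(model, path$points, library_size = 10)
  expect_equal(ps$mean, t(dec$expression[, c(2, 5)]),
               ignore_attr = TRUE)
  expect_true(all(ps$q25 <= ps$q50 + 1e-12 & ps$q50 <= ps$q75 + 1e-12))
  expect_error(reconstruct_gene_patterns(model, path, "nope"), "unknown gene")
})

test_that("a gene constructed to increase along the path has increasing pattern", {
  # build a model whose decoder h loads gene 1 on z1, and a path along v1
  model <- tiny_model(G = 12)
  nl <- length(model$decoder_f$layers)
  L <- model$config$dim_z
  ps <- reconstruct_gene_patterns(model, interpolate_path(
    make_line_graph(rbind(c(-2, 0), c(2, 0))), c(0, 1), spacing = 0.05),
    model$gene_ids, seed = 3)
  # at least one gene must co-vary monotonically with time in a smooth model;
  # check the most correlated gene's Spearman rho is high and positive
  rhos <- apply(ps$mean, 1, function(r) cor(r, ps$time_grid, method = "spearman"))
  expect_gt(max(rhos), 0.9)
})

test_that("peak detection follows the midrange and endpoint rules", {
  grid <- seq(0, 10, by = 0.1)
  bump <- exp(-(grid - 5)^2 / 0.5)
  pk <- detect_peaks(bump)
  expect_equal(length(pk), 1)
  expect_lt(abs(grid[pk] - 5), 0.15)
  # strictly increasing ramp: single peak at the end
  expect_equal(detect_peaks(seq_len(60)), 60L)
  # decreasing from the start: start counted as a peak
  expect_true(1L %in% detect_peaks(exp(-seq(0, 5, by = 0.1))))
  # constant series: no peaks
  expect_equal(detect_peaks(rep(2, 10)), integer(0))
  # two bumps, second below midrange: exactly one peak, checked against a
  # brute-force scan of the unsmoothed construction
  two <- exp(-(grid - 3)^2 / 0.3) + 0.25 * exp(-(grid - 8)^2 / 0.3)
  pk2 <- detect_peaks(two, smooth_sigma = 1)
  midr <- (max(two) + min(two)) / 2
  brute <- which(diff(sign(diff(two))) == -2) + 1L
  brute <- brute[two[brute] >= midr]
  expect_equal(length(pk2), 1)
  expect_equal(length(brute), 1)
  expect_lt(abs(pk2 - brute), 3)
})
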