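# Trajectory construction in the 2D top space: Leiden clustering on the
# latent factors z (they carry the finer cell-state detail), a minimum
# spanning tree over cluster centroids using distances in the top space v
# (which carries the global geometry), marker-scored endpoints, the unique
# tree path between them, linear interpolation into an arc-length
# parameterized polyline whose coordinate is the shared pseudotime, and
# projection of cells onto it.

#' Cluster cells on the latent factors
#'
#' Leiden community detection (modularity objective) on an undirected
#' k-nearest-neighbor graph of z. Deterministic under \code{seed}.
#'
#' @param z numeric matrix (cells x dim_z).
#' @param n_neighbors neighbors for the kNN graph (default 15).
#' @param resolution Leiden resolution parameter (default 0.7).
#' @param seed integer seed.
#' @return Integer vector of contiguous cluster labels 0..K-1.
#' @export
cluster_latent <- function(z, n_neighbors = 15L, resolution = 0.7, seed = 0L) {
  z <- as.matrix(z)
  N <- nrow(z)
  stopifnot(N >= n_neighbors)
  if (all(apply(z, 2, stats::sd) == 0)) {
    warning("all latent vectors identical; returning a single cluster")
    return(rep(0L, N))
  }
  d <- as.matrix(stats::dist(z))
  edges <- integer(0)
  for (i in seq_len(N)) {
    nb <- order(d[i, ])[2:(n_neighbors + 1L)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::simplify(igraph::make_graph(edges, n = N, directed = FALSE))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L)
  labels <- as.integer(igraph::membership(cl))
  as.integer(factor(labels)) - 1L
}

#' Cluster graph: centroids and minimum spanning tree
#'
#' Computes per-cluster centroids in both spaces and the minimum spanning
#' tree of the complete graph on v-centroids with Euclidean edge weights.
#'
#' @param embedding a \code{decipher_embedding} (or a list with matrices
#'   \code{v} and \code{z}).
#' @param labels integer cluster labels 0..K-1 per cell.
#' @return An object of class \code{cluster_graph}: \code{labels},
#'   \code{centroids_v} (K x dim_v), \code{centroids_z}, \code{mst_edges}
#'   (data.frame from, to, weight; 0-based cluster ids), and the igraph tree.
#' @export
build_cluster_graph <- function(embedding, labels) {
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  stopifnot(length(ks) >= 2)
  cent <- function(M) {
    t(vapply(ks, function(k) colMeans(M[labels == k, , drop = FALSE]),
             numeric(ncol(M))))
  }
  cv <- cent(embedding$v)
  cz <- cent(embedding$z)
  D <- as.matrix(stats::dist(cv))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  el <- igraph::as_edgelist(tree, names = FALSE)
  mst_edges <- data.frame(from = ks[el[, 1]], to = ks[el[, 2]],
                          weight = igraph::E(tree)$weight)
  structure(list(labels = labels, cluster_ids = ks,
                 centroids_v = cv, centroids_z = cz,
                 mst_edges = mst_edges, tree = tree),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat(sprintf("cluster_graph: %d clusters, MST with %d edges (total weight %.3f)\n",
              length(x$cluster_ids), nrow(x$mst_edges), sum(x$mst_edges$weight)))
  invisible(x)
}

# Mean marker score per cluster: mean over markers of log1p
# median-normalized expression, averaged within cluster.
marker_scores <- function(graph, counts, markers) {
  missing <- setdiff(markers, counts$gene_ids)
  if (length(missing) > 0) {
    stop("marker genes absent: ", paste(missing, collapse = ", "))
  }
  expr <- normalized_expression(counts)[, markers, drop = FALSE]
  sc <- vapply(graph$cluster_ids, function(k) {
    mean(expr[graph$labels == k, , drop = FALSE])
  }, numeric(1))
  stats::setNames(sc, graph$cluster_ids)
}

#' Find the trajectory's cluster path in the spanning tree
#'
#' The start (end) cluster is the argmax over clusters of the mean
#' normalized expression of the start (end) marker genes; the path is the
#' unique tree path between them. Explicit endpoints can be given instead
#' of markers via \code{start_cluster}/\code{end_cluster} (trajectories may
#' also be specified fully manually, see \code{\link{interpolate_path}}).
#'
#' @param graph a \code{cluster_graph}.
#' @param counts the \code{\link{count_matrix}} the embedding came from.
#' @param start_markers,end_markers character vectors of marker genes.
#' @param start_cluster,end_cluster optional explicit cluster ids
#'   (override markers).
#' @return Integer vector of cluster ids along the path.
#' @export
find_path <- function(graph, counts = NULL, start_markers = NULL,
                      end_markers = NULL, start_cluster = NULL,
                      end_cluster = NULL) {
  stopifnot(inherits(graph, "cluster_graph"))
  s_scores <- e_scores <- NULL
  if (is.null(start_cluster)) {
    s_scores <- marker_scores(graph, counts, start_markers)
    start_cluster <- as.integer(names(s_scores)[which.max(s_scores)])
  }
  if (is.null(end_cluster)) {
    e_scores <- marker_scores(graph, counts, end_markers)
    end_cluster <- as.integer(names(e_scores)[which.max(e_scores)])
  }
  if (start_cluster == end_cluster) {
    err <- structure(class = c("decipher_path_error", "error", "condition"),
                     list(message = paste0("start and end markers select the same cluster (",
                                           start_cluster, ")"),
                          call = sys.call(),
                          start_scores = s_scores, end_scores = e_scores))
    stop(err)
  }
  si <- match(start_cluster, graph$cluster_ids)
  ei <- match(end_cluster, graph$cluster_ids)
  p <- igraph::shortest_paths(graph$tree, from = si, to = ei)$vpath[[1]]
  graph$cluster_ids[as.integer(p)]
}

#' Interpolate a cluster path into an arc-length parameterized polyline
#'
#' Linear interpolation through the ordered v-centroids, sampled every
#' \code{spacing} arc-length units with the vertices always included; the
#' running arc length is the trajectory's shared pseudotime coordinate.
#'
#' @param graph a \code{cluster_graph}.
#' @param cluster_sequence ordered cluster ids (length >= 2).
#' @param spacing sampling interval in v units (default 0.05).
#' @param condition optional condition label carried on the path.
#' @return An object of class \code{trajectory_path}: \code{cluster_sequence},
#'   \code{points} (M x 2 polyline vertices), \code{times} (cumulative arc
#'   length, starting at 0), \code{condition}.
#' @export
interpolate_path <- function(graph, cluster_sequence, spacing = 0.05,
                             condition = NULL) {
  stopifnot(length(cluster_sequence) >= 2, spacing > 0)
  idx <- match(cluster_sequence, graph$cluster_ids)
  if (anyNA(idx)) stop("unknown cluster id in sequence")
  verts <- graph$centroids_v[idx, , drop = FALSE]
  seg_len <- sqrt(rowSums((verts[-1, , drop = FALSE] -
                           verts[-nrow(verts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  times <- sort(unique(c(seq(0, total, by = spacing), cum)))
  pts <- vapply(seq_len(ncol(verts)), function(j) {
    stats::approx(cum, verts[, j], xout = times, ties = "ordered")$y
  }, numeric(length(times)))
  structure(list(cluster_sequence = cluster_sequence,
                 points = matrix(pts, ncol = ncol(verts)),
                 times = times, condition = condition),
            class = "trajectory_path")
}

#' @export
print.trajectory_path <- function(x, ...) {
  cat(sprintf("trajectory_path%s: clusters [%s], %d points, total length %.3f\n",
              if (is.null(x$condition)) "" else paste0(" (", x$condition, ")"),
              paste(x$cluster_sequence, collapse = " > "),
              nrow(x$points), max(x$times)))
  invisible(x)
}

#' Assign each cell the pseudotime of its nearest trajectory point
#'
#' Projects every cell's v onto its own condition's trajectory polyline
#' (nearest discretized point; ties broken toward the smaller time). Because
#' conditions are co-embedded, the resulting times are directly comparable
#' across conditions without any warping.
#'
#' @param embedding a \code{decipher_embedding}.
#' @param paths a named list of \code{trajectory_path}, one per condition;
#'   or a single path applied to all cells.
#' @param condition_labels per-cell condition labels matching \code{names(paths)}
#'   (ignored when a single path is given).
#' @return data.frame with \code{cell_id}, \code{condition}, \code{time},
#'   \code{distance}.
#' @export
assign_time <- function(embedding, paths, condition_labels = NULL) {
  if (inherits(paths, "trajectory_path")) {
    paths <- list(all = paths)
    condition_labels <- rep("all", nrow(embedding$v))
  }
  condition_labels <- as.character(condition_labels)
  absent <- setdiff(unique(condition_labels), names(paths))
  if (length(absent) > 0) {
    stop("no trajectory for condition(s): ", paste(absent, collapse = ", "))
  }
  n <- nrow(embedding$v)
  time <- numeric(n); dist_to <- numeric(n)
  for (cond in names(paths)) {
    sel <- which(condition_labels == cond)
    if (length(sel) == 0) next
    P <- paths[[cond]]$points
    tt <- paths[[cond]]$times
    vv <- embedding$v[sel, , drop = FALSE]
    # squared distances cells x path points
    d2 <- outer(rowSums(vv^2), rowSums(P^2), "+") - 2 * tcrossprod(vv, P)
    nearest <- apply(d2, 1, which.min)  # which.min takes the first: earlier time
    time[sel] <- tt[nearest]
    dist_to[sel] <- sqrt(pmax(d2[cbind(seq_along(sel), nearest)], 0))
  }
  data.frame(cell_id = embedding$cell_ids, condition = condition_labels,
             time = time, distance = dist_to)
}

#' Reconstruct gene expression patterns along a trajectory
#'
#' Decodes the mean expression at every point of the path and adds
#' interquartile uncertainty bands from sampling the v-to-z decoder's
#' conditional distribution.
#'
#' @param model a fitted \code{decipher_model}.
#' @param path a \code{trajectory_path}.
#' @param genes genes to reconstruct (must belong to the model).
#' @param n_samples z samples for the uncertainty bands (default 100).
#' @param library_size output scale (default 1: normalized expression).
#' @param seed integer seed.
#' @return An object of class \code{gene_pattern_set}: \code{genes},
#'   \code{time_grid}, matrices \code{mean}, \code{q25}, \code{q50},
#'   \code{q75} (gene x time), \code{library_size}, \code{condition}.
#' @export
reconstruct_gene_patterns <- function(model, path, genes, n_samples = 100L,
                                      library_size = 1, seed = 0L) {
  stopifnot(inherits(path, "trajectory_path"))
  unknown <- setdiff(genes, model$gene_ids)
  if (length(unknown) > 0) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  gi <- match(genes, model$gene_ids)
  dec <- decipher_decode(model, path$points, library_size = library_size)
  bands <- decipher_decode_uncertainty(model, path$points,
                                       n_samples = n_samples,
                                       library_size = library_size, seed = seed)
  pick <- function(M) {
    out <- t(M[, gi, drop = FALSE])
    rownames(out) <- genes
    out
  }
  structure(list(genes = genes, time_grid = path$times,
                 mean = pick(dec$expression),
                 q25 = pick(bands$q25), q50 = pick(bands$q50),
                 q75 = pick(bands$q75),
                 library_size = library_size, condition = path$condition),
            class = "gene_pattern_set")
}

#' @export
print.gene_pattern_set <- function(x, ...) {
  cat(sprintf("gene_pattern_set: %d genes on %d time points%s\n",
              length(x$genes), length(x$time_grid),
              if (is.null(x$condition)) "" else paste0(" (", x$condition, ")")))
  invisible(x)
}

#' Detect expression peaks along a pattern
#'
#' Smooths the series with a 1D Gaussian filter (detection only), finds
#' local maxima where the first difference changes sign from positive to
#' negative, and keeps those at or above the midrange (mean of the minimum
#' and maximum). The start is added when it is above threshold with a
#' negative initial derivative, or when the global maximum sits at the
#' start; the end is added when the global maximum sits at the end. A
#' constant series has no peaks.
#'
#' @param pattern numeric series on a uniform time grid (length >= 3).
#' @param smooth_sigma Gaussian kernel standard deviation, in grid units
#'   (default 3).
#' @return Integer vector of peak positions (indices into the grid).
#' @export
detect_peaks <- function(pattern, smooth_sigma = 3) {
  n <- length(pattern)
  stopifnot(n >= 3)
  if (max(pattern) == min(pattern)) return(integer(0))
  sm <- gaussian_smooth(pattern, smooth_sigma)
  midrange <- (max(sm) + min(sm)) / 2
  d <- diff(sm)
  interior <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  peaks <- interior[sm[interior] >= midrange]
  gmax <- which.max(sm)
  if ((sm[1] >= midrange && d[1] < 0) || gmax == 1L) peaks <- c(1L, peaks)
  if (gmax == n) peaks <- c(peaks, n)
  sort(unique(peaks))
}

# Truncated, renormalized Gaussian smoothing on a uniform grid.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(x[lo:hi] * w) / sum(w)
  }
  out
}
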