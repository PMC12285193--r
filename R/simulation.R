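# Ground-truth trajectory simulator and embedding-quality metrics.
# Cells are sampled uniformly by arc length along a forked 2D trajectory
# (trunk plus two arms), thinned inside designated transition windows to
# emulate rare intermediate states, perturbed with isotropic Gaussian noise,
# and mapped to high-dimensional expression through a fixed random neural
# network. The first coordinate of the true state is the pseudotime.

#' Default forked trajectory
#'
#' Trunk from (0,0) to (4,0), arms to (8, 2) and (8, -2); the transition
#' windows (where cells are thinned) cover first-coordinate values in
#' [3.5, 4.5] around the fork point.
#'
#' @return A fork specification: list of branches (each a 2-column matrix of
#'   polyline vertices) and \code{transition_window} (range of the first
#'   coordinate).
#' @export
default_fork <- function() {
  list(branches = list(
         up = rbind(c(0, 0), c(4, 0), c(8, 2)),
         down = rbind(c(0, 0), c(4, 0), c(8, -2))),
       transition_window = c(3.5, 4.5))
}

polyline_point <- function(verts, at) {
  seg <- sqrt(rowSums((verts[-1, , drop = FALSE] -
                       verts[-nrow(verts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  at <- min(max(at, 0), cum[length(cum)])
  i <- findInterval(at, cum, rightmost.closed = TRUE)
  w <- (at - cum[i]) / seg[i]
  verts[i, ] + w * (verts[i + 1, ] - verts[i, ])
}

#' Simulate cell states along a forked trajectory
#'
#' Samples \code{n} candidate locations uniformly by arc length (branch
#' chosen uniformly), keeps locations whose unperturbed first coordinate
#' falls inside the transition window independently with probability
#' \code{transition_density}, and perturbs survivors with isotropic
#' Gaussian noise.
#'
#' @param n number of candidate cells (>= 10); the returned dataset has the
#'   surviving cells.
#' @param fork a fork specification (see \code{\link{default_fork}}).
#' @param transition_density retention probability inside the transition
#'   window, in [0, 1] (default 0.05).
#' @param noise_sigma state noise standard deviation (default 0.1).
#' @param seed integer seed.
#' @return An object of class \code{simulated_dataset}: \code{true_states}
#'   (N x 2, post-thinning, pre-noise), \code{pseudotime} (first coordinate
#'   of the true state), \code{noisy_states} (N x 2), \code{branch_label},
#'   \code{spec} (all parameters). Expression is added by
#'   \code{\link{map_to_expression}}.
#' @export
simulate_states <- function(n, fork = default_fork(), transition_density = 0.05,
                            noise_sigma = 0.1, seed = 0L) {
  stopifnot(n >= 10)
  if (transition_density < 0 || transition_density > 1) {
    stop("transition_density must lie in [0, 1]")
  }
  set.seed(seed)
  branches <- fork$branches
  lens <- vapply(branches, function(b) {
    sum(sqrt(rowSums((b[-1, , drop = FALSE] - b[-nrow(b), , drop = FALSE])^2)))
  }, numeric(1))
  bidx <- sample.int(length(branches), n, replace = TRUE)
  pos <- runif(n) * lens[bidx]
  states <- t(vapply(seq_len(n),
                     function(i) polyline_point(branches[[bidx[i]]], pos[i]),
                     numeric(2)))
  w <- fork$transition_window
  in_window <- states[, 1] >= w[1] & states[, 1] <= w[2]
  keep <- !in_window | (runif(n) < transition_density)
  states <- states[keep, , drop = FALSE]
  bidx <- bidx[keep]
  noisy <- states + matrix(rnorm(length(states), sd = noise_sigma),
                           nrow(states), 2)
  structure(list(true_states = states,
                 pseudotime = states[, 1],
                 noisy_states = noisy,
                 branch_label = names(branches)[bidx],
                 expression = NULL,
                 spec = list(n = n, fork = fork,
                             transition_density = transition_density,
                             noise_sigma = noise_sigma, seed = seed)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d cells (of %d sampled), density %.2g, sigma %.2g\n",
              nrow(x$true_states), x$spec$n, x$spec$transition_density,
              x$spec$noise_sigma))
  invisible(x)
}

#' Map 2D states to high-dimensional expression with a fixed random network
#'
#' A feed-forward network (two ReLU hidden layers of width 64 by default)
#' with weights drawn once from \code{seed} is applied row-wise; identical
#' states always map to identical outputs. A softplus output keeps the
#' values non-negative so they can serve as expression rates.
#'
#' @param states N x 2 matrix of (noisy) cell states.
#' @param d output dimension (default 500).
#' @param hidden hidden layer widths (default c(64, 64)).
#' @param seed integer seed for the network weights.
#' @return N x d matrix of non-negative expression values.
#' @export
map_to_expression <- function(states, d = 500L, hidden = c(64L, 64L),
                              seed = 0L) {
  stopifnot(d >= 2)
  states <- as.matrix(states)
  set.seed(seed)
  net <- mlp_new(c(ncol(states), hidden, d), activation = "relu",
                 batchnorm = FALSE, init_sd = "fan_in", bias_init = TRUE)
  softplus(mlp_forward(net, states, train = FALSE)$out)
}

#' Simulate a forked-trajectory count dataset
#'
#' Convenience wrapper: simulates states, maps them to expression rates,
#' and draws Poisson counts at a target mean library size, giving raw
#' counts the generative model can be fitted to.
#'
#' @inheritParams simulate_states
#' @param d number of genes (default 500).
#' @param mean_library target mean library size (default 2500).
#' @return The \code{simulated_dataset} with \code{expression} (the rates)
#'   and \code{counts} (a \code{\link{count_matrix}} with the branch label
#'   as annotation) attached.
#' @export
simulate_fork_counts <- function(n, fork = default_fork(),
                                 transition_density = 0.05, noise_sigma = 0.1,
                                 d = 500L, mean_library = 2500, seed = 0L) {
  sim <- simulate_states(n, fork, transition_density, noise_sigma, seed)
  rates <- map_to_expression(sim$noisy_states, d = d, seed = seed + 1L)
  rates <- rates / mean(rowSums(rates)) * mean_library
  set.seed(seed + 2L)
  counts <- matrix(stats::rpois(length(rates), as.vector(rates)),
                   nrow(rates), ncol(rates))
  keep <- rowSums(counts) > 0
  sim$true_states <- sim$true_states[keep, , drop = FALSE]
  sim$pseudotime <- sim$pseudotime[keep]
  sim$noisy_states <- sim$noisy_states[keep, , drop = FALSE]
  sim$branch_label <- sim$branch_label[keep]
  sim$expression <- rates[keep, , drop = FALSE]
  sim$counts <- count_matrix(counts[keep, , drop = FALSE],
                             annotations = data.frame(branch = sim$branch_label[keep]))
  sim
}

#' Global structure preservation between a ground-truth and a learned space
#'
#' Clusters the ground-truth states with (seeded, multi-start) k-means, sums
#' all cross-cluster pairwise Euclidean distances in both spaces, and
#' returns the mean over clusters of the Kendall-tau correlation between
#' each cluster's distance profile in the two spaces. Equals 1 for any
#' isometric (or uniformly scaled) copy; invariant to rotations,
#' reflections, and positive scalings of either space.
#'
#' @param true_states N x 2 ground-truth states.
#' @param latent N x D learned representation, row-aligned with
#'   \code{true_states}.
#' @param n_clusters number of k-means clusters (default 20).
#' @param seed integer seed for k-means.
#' @return Scalar in [-1, 1].
#' @export
global_preservation <- function(true_states, latent, n_clusters = 20L,
                                seed = 0L) {
  true_states <- as.matrix(true_states); latent <- as.matrix(latent)
  stopifnot(nrow(true_states) == nrow(latent), nrow(true_states) >= n_clusters)
  set.seed(seed)
  km <- try(stats::kmeans(true_states, centers = n_clusters, nstart = 10,
                          iter.max = 50), silent = TRUE)
  if (inherits(km, "try-error")) {
    km <- stats::kmeans(true_states, centers = n_clusters, nstart = 25,
                        iter.max = 100)
  }
  cl <- km$cluster
  dsum <- function(M) {
    D <- as.matrix(stats::dist(M))
    agg <- rowsum(D, cl)           # clusters x N
    t(rowsum(t(agg), cl))          # clusters x clusters, sums over C_i x C_j
  }
  D1 <- dsum(true_states)
  D2 <- dsum(latent)
  # each cluster's profile of distances to the *other* clusters; the
  # intra-cluster entry is excluded (it is minimal in any embedding and
  # would cap the attainable correlation range)
  taus <- vapply(seq_len(n_clusters), function(i) {
    stats::cor(D1[i, -i], D2[i, -i], method = "kendall")
  }, numeric(1))
  mean(taus)
}

# Mean pairwise Euclidean distance between two groups of rows.
group_distance <- function(M, idx1, idx2) {
  A <- M[idx1, , drop = FALSE]; B <- M[idx2, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  mean(sqrt(pmax(d2, 0)))
}

#' Ordering score of annotated states in a latent space
#'
#' For an ordered list of cell-state labels, the ratio of the summed
#' distances between non-consecutive states to the summed distances between
#' consecutive states (distances between states are mean pairwise cell
#' distances). By the triangle inequality the ratio is maximized when the
#' states fall on a line in the stated order; higher is better.
#'
#' @param latent N x D matrix.
#' @param labels per-cell state labels.
#' @param ordered_list the expected order of (a subset of) the labels
#'   (length >= 3).
#' @return Scalar ratio.
#' @export
ordering_score <- function(latent, labels, ordered_list) {
  stopifnot(length(ordered_list) >= 3)
  labels <- as.character(labels)
  missing <- setdiff(ordered_list, labels)
  if (length(missing) > 0) stop("labels absent: ", paste(missing, collapse = ", "))
  latent <- as.matrix(latent)
  idx <- lapply(ordered_list, function(l) which(labels == l))
  m <- length(ordered_list)
  num <- 0; den <- 0
  for (i1 in seq_len(m - 1)) {
    for (i2 in (i1 + 1):m) {
      d <- group_distance(latent, idx[[i1]], idx[[i2]])
      if (i2 - i1 == 1) den <- den + d else num <- num + d
    }
  }
  num / den
}

#' Divergence score between two condition trajectories
#'
#' Rewards geometries in which the two conditions' non-anchor states are
#' mutually far apart while the designated anchor states (the shared
#' immature/early origin) remain close:
#' sum over non-anchor cross-condition state pairs of their distance, minus
#' twice the distance between the two anchor states.
#'
#' @param latent N x D matrix.
#' @param labels per-cell state labels.
#' @param states1,states2 state labels of condition 1 / condition 2
#'   (each includes its anchor).
#' @param anchor_pair length-2 vector: the anchor state of condition 1 and
#'   of condition 2.
#' @return Signed scalar; higher is better.
#' @export
divergence_score <- function(latent, labels, states1, states2, anchor_pair) {
  labels <- as.character(labels)
  if (!all(anchor_pair %in% labels)) {
    stop("anchor state(s) absent: ",
         paste(setdiff(anchor_pair, labels), collapse = ", "))
  }
  latent <- as.matrix(latent)
  idx <- function(l) which(labels == l)
  total <- 0
  for (c1 in setdiff(states1, anchor_pair[1])) {
    for (c2 in setdiff(states2, anchor_pair[2])) {
      total <- total + group_distance(latent, idx(c1), idx(c2))
    }
  }
  total - 2 * group_distance(latent, idx(anchor_pair[1]), idx(anchor_pair[2]))
}

#' Per-cell mutation proportion among nearest neighbors
#'
#' The smoothed mutant fraction \code{m / (m + w + 1e-10)} where m and w
#' count mutant and wild-type calls among each cell's k nearest neighbors.
#'
#' @param m,w non-negative counts of mutant / wild-type neighbors
#'   (vectorized).
#' @return Proportions in [0, 1).
#' @export
mutation_proportion <- function(m, w) {
  stopifnot(all(m >= 0), all(w >= 0))
  m / (m + w + 1e-10)
}

#' Neighborhood mutation proportion from labeled cells
#'
#' Finds each cell's k nearest neighbors in a truncated-SVD space of
#' median-normalized expression and applies
#' \code{\link{mutation_proportion}} to the neighbor label counts. Cells
#' with status \code{NA} count as neither mutant nor wild type.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param status per-cell character vector: "mutant", "wildtype", or NA.
#' @param k neighbors (default 30).
#' @param n_components truncated-SVD components (default 100, capped at the
#'   matrix rank).
#' @return Numeric vector of per-cell proportions.
#' @export
neighborhood_mutation_proportion <- function(counts, status, k = 30L,
                                             n_components = 100L) {
  stopifnot(inherits(counts, "count_matrix"))
  N <- nrow(counts$counts)
  if (k > N - 1) stop("k must be smaller than the number of cells")
  lib <- counts$library_sizes; lib[lib == 0] <- 1
  X <- counts$counts / lib * stats::median(counts$library_sizes)
  nc <- min(n_components, dim(X) - 1L)
  sv <- svd(X, nu = nc, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(nc)], nc)
  D <- as.matrix(stats::dist(emb))
  diag(D) <- Inf
  status <- as.character(status)
  vapply(seq_len(N), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mutation_proportion(sum(status[nb] == "mutant", na.rm = TRUE),
                        sum(status[nb] == "wildtype", na.rm = TRUE))
  }, numeric(1))
}
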