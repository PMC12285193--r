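# Probabilistic basis decomposition of gene patterns across conditions.
# Each observed pattern mu_{g,c}(t) is modeled as s_{g,c} * sum_k beta_{g,c,k}
# b_k(t) plus white Gaussian noise, where the K basis functions b_k are
# neural networks (1 -> 32 -> 32 -> 1, tanh) drawn from a near-Gaussian-process
# prior (weight variance = 1/fan-in), squashed to (0, 1] and max-normalized,
# and the weights beta are Dirichlet(eta) simplex vectors. Inference is
# stochastic-gradient variational inference: a logistic-normal guide (additive
# log-ratio parameterization) for beta, point estimates for the basis network
# weights, the log gene scales, and the log noise variance.

#' Pattern matrix container
#'
#' Gene x condition x time array of expression patterns sharing one time
#' grid, e.g. the mean patterns reconstructed along per-condition
#' trajectories.
#'
#' @param values numeric array (gene x condition x T) or, for a single
#'   condition, a gene x T matrix.
#' @param time_grid numeric vector of length T.
#' @param gene_ids,condition_ids identifiers (defaults from dimnames).
#' @return An object of class \code{pattern_matrix}.
#' @export
pattern_matrix <- function(values, time_grid, gene_ids = NULL,
                           condition_ids = NULL) {
  if (is.matrix(values)) values <- array(values, c(nrow(values), 1, ncol(values)))
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(time_grid))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite pattern value at gene %d, condition %d, time %d",
                 bad[1], bad[2], bad[3]))
  }
  if (is.null(gene_ids)) gene_ids <- dimnames(values)[[1]]
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(dim(values)[1]))
  if (is.null(condition_ids)) condition_ids <- dimnames(values)[[2]]
  if (is.null(condition_ids)) condition_ids <- paste0("condition_", seq_len(dim(values)[2]))
  dimnames(values) <- list(gene_ids, condition_ids, NULL)
  structure(list(values = values, time_grid = as.numeric(time_grid),
                 gene_ids = gene_ids, condition_ids = condition_ids),
            class = "pattern_matrix")
}

#' Assemble a pattern matrix from per-condition gene pattern sets
#'
#' Resamples each condition's reconstructed patterns onto a shared uniform
#' time grid by linear interpolation.
#'
#' @param pattern_sets named list of \code{gene_pattern_set} (one per
#'   condition; names are the condition ids).
#' @param n_grid number of uniform grid points (default 100).
#' @return A \code{pattern_matrix}.
#' @export
patterns_to_matrix <- function(pattern_sets, n_grid = 100L) {
  genes <- pattern_sets[[1]]$genes
  conds <- names(pattern_sets)
  tmax <- max(vapply(pattern_sets, function(p) max(p$time_grid), numeric(1)))
  grid <- seq(0, tmax, length.out = n_grid)
  vals <- array(NA_real_, c(length(genes), length(conds), n_grid))
  for (ci in seq_along(conds)) {
    p <- pattern_sets[[ci]]
    stopifnot(identical(p$genes, genes))
    for (gi in seq_along(genes)) {
      vals[gi, ci, ] <- stats::approx(p$time_grid, p$mean[gi, ], xout = grid,
                                      rule = 2)$y
    }
  }
  pattern_matrix(vals, grid, gene_ids = genes, condition_ids = conds)
}

#' Basis decomposition configuration
#'
#' @param K number of basis functions (default 5).
#' @param eta symmetric Dirichlet concentration; values below 1 favor sparse
#'   weights and hence dominant, interpretable bases (default 0.25).
#' @param hidden_width hidden width of each basis network (default 32).
#' @param noise_variance_init initial white-noise variance (default 0.01).
#' @param n_steps gradient steps (default 3000).
#' @param learning_rate Adam learning rate (default 0.02).
#' @param seed integer seed.
#' @return An object of class \code{basis_config}.
#' @export
basis_config <- function(K = 5L, eta = 0.25, hidden_width = 32L,
                         noise_variance_init = 0.01, n_steps = 3000L,
                         learning_rate = 0.02, seed = 0L) {
  stopifnot(K >= 2, eta > 0, hidden_width >= 1, noise_variance_init > 0,
            n_steps >= 1, learning_rate > 0)
  structure(list(K = as.integer(K), eta = eta,
                 hidden_width = as.integer(hidden_width),
                 noise_variance_init = noise_variance_init,
                 n_steps = as.integer(n_steps),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "basis_config")
}

# Evaluate one basis network on a normalized grid column; returns the
# max-normalized curve and the pieces needed for backprop.
basis_net_forward <- function(net, tcol) {
  fw <- mlp_forward(net, tcol, train = FALSE)
  q <- sigmoid(fw$out[, 1])
  M <- max(q)
  list(b = q / M, q = q, M = M, imax = which.max(q), cache = fw$cache)
}

#' Sample basis functions from the prior
#'
#' Draws each basis network's weights and biases from centered normals with
#' variance 1/fan-in, evaluates on the grid, squashes through a logistic to
#' (0, 1), and divides by the maximum so each basis attains exactly 1.
#'
#' @param config a \code{\link{basis_config}} (uses K and hidden_width).
#' @param time_grid numeric grid (length >= 2); internally rescaled to [0, 1].
#' @param seed integer seed.
#' @return K x T matrix of basis values in [0, 1], each row with max 1.
#' @export
sample_basis_prior <- function(config, time_grid, seed = 0L) {
  stopifnot(length(time_grid) >= 2)
  set.seed(seed)
  tcol <- matrix(normalize_grid(time_grid), ncol = 1)
  H <- config$hidden_width
  B <- matrix(NA_real_, config$K, length(time_grid))
  for (k in seq_len(config$K)) {
    net <- mlp_new(c(1L, H, H, 1L), activation = "tanh", batchnorm = FALSE,
                   init_sd = "fan_in", bias_init = TRUE)
    B[k, ] <- basis_net_forward(net, tcol)$b
  }
  B
}

normalize_grid <- function(time_grid) {
  rng <- range(time_grid)
  if (diff(rng) == 0) return(rep(0, length(time_grid)))
  (time_grid - rng[1]) / diff(rng)
}

#' Log density of the symmetric Dirichlet distribution
#'
#' \code{log p(beta | eta)} with normalizer
#' \code{B(eta) = Gamma(eta)^K / Gamma(K eta)}. For \code{eta < 1} the
#' density diverges at the simplex boundary; a zero coordinate then yields
#' \code{-Inf} (an explicit flag value, not an error).
#'
#' @param beta simplex vector (non-negative, sums to 1 within 1e-8).
#' @param eta positive concentration.
#' @return Log density (possibly \code{-Inf} or \code{Inf} on the boundary).
#' @export
dirichlet_log_density <- function(beta, eta) {
  stopifnot(eta > 0, all(beta >= 0))
  if (abs(sum(beta) - 1) > 1e-8) stop("beta must lie on the simplex")
  K <- length(beta)
  if (any(beta == 0)) {
    if (eta < 1) return(-Inf)
    if (eta == 1) return(lgamma(K))  # uniform density, constant on the simplex
  }
  lgamma(K * eta) - K * lgamma(eta) + sum((eta - 1) * log(beta))
}

#' Fit the basis decomposition
#'
#' Maximizes the evidence lower bound of the white-noise Gaussian-process
#' observation model by full-batch stochastic-gradient VI (one
#' reparameterized sample of each weight vector per step, Adam updates).
#' Because the kernel is white noise the likelihood factorizes over grid
#' points into independent Gaussians of variance sigma^2.
#'
#' @param patterns a \code{\link{pattern_matrix}}.
#' @param config a \code{\link{basis_config}}.
#' @param verbose print the loss every 200 steps.
#' @return An object of class \code{basis_fit}: \code{basis_values} (K x T,
#'   max-normalized), \code{weights} (gene x condition x K posterior-mean
#'   simplex vectors), \code{scales} (gene x condition), \code{noise_variance},
#'   \code{loss_trace}, plus the grid and identifiers.
#' @export
fit_basis <- function(patterns, config = basis_config(), verbose = FALSE) {
  stopifnot(inherits(patterns, "pattern_matrix"), inherits(config, "basis_config"))
  dims <- dim(patterns$values)
  G <- dims[1]; C <- dims[2]; Tn <- dims[3]
  if (G < 2) stop("need at least 2 genes")
  K <- config$K; eta <- config$eta; H <- config$hidden_width

  # flatten observations to rows = (gene, condition)
  Y <- matrix(aperm(patterns$values, c(3, 1, 2)), nrow = Tn)  # T x (G*C)
  Y <- t(Y)                                                   # (G*C) x T
  n_obs <- G * C
  tcol <- matrix(normalize_grid(patterns$time_grid), ncol = 1)

  set.seed(config$seed)
  nets <- lapply(seq_len(K), function(k) {
    mlp_new(c(1L, H, H, 1L), activation = "tanh", batchnorm = FALSE,
            init_sd = "fan_in", bias_init = TRUE)
  })
  # prior variance per parameter array (1/fan-in), for the MAP term on phi
  prior_var <- lapply(mlp_get_params(nets[[1]]), function(p) {
    if (is.matrix(p)) 1 / nrow(p) else 1  # bias fan-in treated as 1
  })
  m_w <- matrix(0, n_obs, K - 1)              # ALR guide means
  l_w <- matrix(log(0.5), n_obs, K - 1)       # ALR guide log-sds
  log_s <- log(pmax(apply(Y, 1, max), 1e-3))  # scales: recon max is <= 1
  log_sig2 <- log(config$noise_variance_init)

  params <- list(m_w = m_w, l_w = l_w, log_s = log_s, log_sig2 = log_sig2)
  for (k in seq_len(K)) {
    params <- c(params, prefix_names(mlp_get_params(nets[[k]]),
                                     paste0("net", k, ".")))
  }
  opt <- adam_new(params, lr = config$learning_rate)
  loss_trace <- numeric(config$n_steps)

  for (step in seq_len(config$n_steps)) {
    # forward bases
    bf <- lapply(seq_len(K), function(k) basis_net_forward(nets[[k]], tcol))
    B <- do.call(rbind, lapply(bf, `[[`, "b"))  # K x T
    eps <- matrix(rnorm(n_obs * (K - 1)), n_obs, K - 1)
    y <- params$m_w + exp(params$l_w) * eps
    ex <- exp(cbind(y, 0) - apply(cbind(y, 0), 1, max))
    beta <- ex / rowSums(ex)                    # n_obs x K
    s <- exp(params$log_s)
    recon <- (beta %*% B) * s                   # n_obs x T
    sig2 <- exp(params$log_sig2)
    resid <- Y - recon

    nll <- 0.5 * sum(log(2 * pi * sig2) + resid^2 / sig2)
    lp_beta <- sum((eta - 1) * log(beta)) +
      n_obs * (lgamma(K * eta) - K * lgamma(eta))
    lq_beta <- sum(-0.5 * log(2 * pi) - params$l_w - 0.5 * eps^2) -
      sum(log(beta))
    lp_phi <- 0
    for (k in seq_len(K)) {
      pk <- mlp_get_params(nets[[k]])
      lp_phi <- lp_phi - sum(vapply(names(pk), function(nm) {
        sum(pk[[nm]]^2) / (2 * prior_var[[nm]])
      }, numeric(1)))
    }
    loss <- nll - lp_beta + lq_beta - lp_phi
    loss_trace[step] <- loss

    # ---- gradients of the loss ----
    dres <- -resid / sig2                       # d nll / d recon
    grads <- list()
    grads$log_sig2 <- sum(0.5 - resid^2 / (2 * sig2))
    grads$log_s <- rowSums(dres * recon)
    dbeta <- (dres %*% t(B)) * s - eta / beta   # includes Dirichlet + Jacobian
    inner <- rowSums(dbeta * beta)
    dy <- beta[, -K, drop = FALSE] *
      (dbeta[, -K, drop = FALSE] - inner)
    grads$m_w <- dy
    grads$l_w <- dy * exp(params$l_w) * eps - 1  # -1: entropy term of the guide
    dB <- t(beta * s) %*% dres                  # K x T
    for (k in seq_len(K)) {
      q <- bf[[k]]$q; M <- bf[[k]]$M; im <- bf[[k]]$imax
      dq <- dB[k, ] / M
      dq[im] <- dq[im] - sum(dB[k, ] * q) / M^2
      du <- dq * q * (1 - q)
      bk <- mlp_backward(nets[[k]], bf[[k]]$cache, matrix(du, ncol = 1))
      gk <- mlp_grads_as_params(nets[[k]], bk$grads)
      pk <- mlp_get_params(nets[[k]])
      for (nm in names(gk)) {
        gk[[nm]] <- gk[[nm]] + pk[[nm]] / prior_var[[nm]]
      }
      grads <- c(grads, prefix_names(gk, paste0("net", k, ".")))
    }

    st <- adam_step(params, grads, opt)
    params <- st$params; opt <- st$state
    for (k in seq_len(K)) {
      sel <- startsWith(names(params), paste0("net", k, "."))
      pk <- params[sel]
      names(pk) <- substring(names(pk), nchar(paste0("net", k, ".")) + 1)
      nets[[k]] <- mlp_set_params(nets[[k]], pk)
    }
    if (verbose && step %% 200 == 0) {
      message(sprintf("step %5d  loss %.3f  sigma %.4f", step, loss, sqrt(sig2)))
    }
  }

  # posterior mean of beta on the simplex (Monte Carlo over the guide)
  S <- 512L
  beta_mean <- matrix(0, n_obs, K)
  for (s_i in seq_len(S)) {
    eps <- matrix(rnorm(n_obs * (K - 1)), n_obs, K - 1)
    y <- params$m_w + exp(params$l_w) * eps
    ex <- exp(cbind(y, 0) - apply(cbind(y, 0), 1, max))
    beta_mean <- beta_mean + ex / rowSums(ex)
  }
  beta_mean <- beta_mean / S
  beta_mean <- beta_mean / rowSums(beta_mean)  # exact simplex after averaging

  bf <- lapply(seq_len(K), function(k) basis_net_forward(nets[[k]], tcol))
  B <- do.call(rbind, lapply(bf, `[[`, "b"))
  weights <- array(beta_mean, c(G, C, K),
                   dimnames = list(patterns$gene_ids, patterns$condition_ids, NULL))
  scales <- matrix(exp(params$log_s), G, C,
                   dimnames = list(patterns$gene_ids, patterns$condition_ids))
  structure(list(basis_values = B, time_grid = patterns$time_grid,
                 weights = weights, scales = scales,
                 noise_variance = exp(params$log_sig2),
                 loss_trace = loss_trace,
                 gene_ids = patterns$gene_ids,
                 condition_ids = patterns$condition_ids,
                 config = config),
            class = "basis_fit")
}

#' @export
print.basis_fit <- function(x, ...) {
  cat(sprintf("basis_fit: K = %d bases on %d grid points; %d genes x %d conditions\n",
              nrow(x$basis_values), ncol(x$basis_values),
              length(x$gene_ids), length(x$condition_ids)))
  cat(sprintf("  noise sd: %.4g   final loss: %.4g\n",
              sqrt(x$noise_variance), x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Reconstruct one pattern from its decomposition
#'
#' Returns \code{s * (beta' B)} on the fit's time grid.
#'
#' @param fit a \code{basis_fit}.
#' @param gene,condition identifiers present in the fit.
#' @return Numeric series on the grid.
#' @export
reconstruct_pattern <- function(fit, gene, condition) {
  gi <- match(gene, fit$gene_ids)
  ci <- match(condition, fit$condition_ids)
  if (is.na(gi)) stop("unknown gene: ", gene)
  if (is.na(ci)) stop("unknown condition: ", condition)
  fit$scales[gi, ci] * drop(fit$weights[gi, ci, ] %*% fit$basis_values)
}

#' Disruption scores between two conditions
#'
#' Per gene: scale disruption \code{|log s1 - log s2|} (difference in
#' expression magnitude), shape disruption \code{||beta1 - beta2||} (change
#' in temporal dynamics, scale-free), and combined disruption
#' \code{||log(s1 beta1) - log(s2 beta2)||}. Norms are Euclidean over the K
#' coordinates; \code{epsilon} guards the logs against zero weights.
#'
#' @param fit a \code{basis_fit}.
#' @param cond_pair character vector of two condition ids.
#' @param epsilon small positive guard added to beta inside logs
#'   (default 1e-6).
#' @return data.frame with \code{gene}, \code{scale_disruption},
#'   \code{shape_disruption}, \code{combined_disruption}.
#' @export
disruption_scores <- function(fit, cond_pair = fit$condition_ids[1:2],
                              epsilon = 1e-6) {
  stopifnot(length(cond_pair) == 2, epsilon >= 0)
  ci <- match(cond_pair, fit$condition_ids)
  if (anyNA(ci)) stop("unknown condition(s): ",
                      paste(cond_pair[is.na(ci)], collapse = ", "))
  b1 <- fit$weights[, ci[1], , drop = FALSE][, 1, ]
  b2 <- fit$weights[, ci[2], , drop = FALSE][, 1, ]
  if (is.null(dim(b1))) { b1 <- matrix(b1, nrow = 1); b2 <- matrix(b2, nrow = 1) }
  s1 <- fit$scales[, ci[1]]; s2 <- fit$scales[, ci[2]]
  scale_d <- abs(log(s1) - log(s2))
  shape_d <- sqrt(rowSums((b1 - b2)^2))
  comb_d <- sqrt(rowSums((log(s1 * (b1 + epsilon)) -
                          log(s2 * (b2 + epsilon)))^2))
  data.frame(gene = fit$gene_ids, scale_disruption = scale_d,
             shape_disruption = shape_d, combined_disruption = comb_d,
             row.names = NULL)
}
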