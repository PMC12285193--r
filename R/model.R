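# The hierarchical generative model:
#   v ~ N(0, I_dv)                      2D top components (visualization space)
#   z | v ~ N(f_mean(v), f_var(v))      latent factors, f a one-hidden-layer MLP
#   mu = softmax(W z + b)               linear decoder to normalized expression
#   x_g | z ~ NB(mu_g * l, theta_g)     raw counts, per-gene dispersion
# Inference is amortized: q(z|x) and q(v|z,x) are diagonal Gaussians whose
# moments come from encoder MLPs; the ELBO carries a weight beta on the prior
# term of v. Encoders see log1p(counts); the likelihood sees raw counts.

.var_floor <- 1e-4

# Initialize an untrained model. Draws weights from the current RNG stream.
decipher_model_init <- function(G, config) {
  L <- config$dim_z; dv <- config$dim_v
  if (!(dv <= L && L < G)) stop("need dim_v <= dim_z < G")
  model <- list(
    config = config,
    gene_ids = paste0("gene_", seq_len(G)),
    decoder_f = mlp_new(c(dv, config$hidden_v_to_z, 2L * L),
                        activation = "relu", batchnorm = TRUE),
    decoder_h = list(W = matrix(rnorm(L * G, sd = sqrt(1 / L)), L, G),
                     b = numeric(G)),
    log_theta = numeric(G),
    encoder_z = mlp_new(c(G, config$hidden_x_to_z, 2L * L),
                        activation = "relu", batchnorm = TRUE),
    encoder_v = mlp_new(c(G + L, config$hidden_xz_to_v, 2L * dv),
                        activation = "relu", batchnorm = TRUE),
    training_log = NULL)
  class(model) <- "decipher_model"
  model
}

row_softmax <- function(a) {
  a <- a - apply(a, 1, max)
  e <- exp(a)
  e / rowSums(e)
}

# Decoder h: latent factors -> normalized expression (rows sum to 1).
decode_h <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  row_softmax(sweep(z %*% model$decoder_h$W, 2, model$decoder_h$b, "+"))
}

# Split a (mean | raw-variance) network output; variances go through
# softplus with a small floor to stay strictly positive.
split_moments <- function(out) {
  d <- ncol(out) / 2L
  list(mean = out[, seq_len(d), drop = FALSE],
       raw = out[, d + seq_len(d), drop = FALSE],
       var = softplus(out[, d + seq_len(d), drop = FALSE]) + .var_floor)
}

#' Sample cells from the generative model
#'
#' Draws \code{n_cells} cells: top components v from a standard normal,
#' latent factors z from the conditional Gaussian given by the v-to-z
#' decoder, normalized means from the softmax decoder, and raw counts from
#' the negative binomial with per-gene dispersion.
#'
#' @param model a \code{decipher_model} (trained or freshly initialized).
#' @param n_cells number of cells to draw.
#' @param library_sizes positive reals, length \code{n_cells} (or length 1,
#'   recycled).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list with \code{counts} (a \code{\link{count_matrix}}) and the
#'   true latents \code{v}, \code{z}, and normalized means \code{mu}.
#' @export
decipher_generate <- function(model, n_cells, library_sizes = 2000, seed = 0L) {
  stopifnot(inherits(model, "decipher_model"), n_cells >= 1)
  library_sizes <- rep_len(library_sizes, n_cells)
  bad <- which(library_sizes <= 0)
  if (length(bad) > 0) {
    stop("non-positive library size for cell index ", bad[1])
  }
  set.seed(seed)
  dv <- model$config$dim_v; L <- model$config$dim_z
  G <- length(model$gene_ids)
  v <- matrix(rnorm(n_cells * dv), n_cells, dv)
  fo <- split_moments(mlp_forward(model$decoder_f, v, train = FALSE)$out)
  z <- fo$mean + sqrt(fo$var) * matrix(rnorm(n_cells * L), n_cells, L)
  mu <- decode_h(model, z)
  theta <- exp(model$log_theta)
  m <- sweep(mu, 1, library_sizes, "*")
  counts <- matrix(stats::rnbinom(n_cells * G,
                                  size = rep(theta, each = n_cells),
                                  mu = as.vector(m)),
                   n_cells, G)
  colnames(counts) <- model$gene_ids
  list(counts = count_matrix(counts, gene_ids = model$gene_ids),
       v = v, z = z, mu = mu)
}

#' Decode top components into expected expression
#'
#' Maps points of the top space v through the mean of the v-to-z decoder and
#' the softmax decoder: \code{z = f_mean(v)}, \code{mu = h(z)} (each row of
#' mu sums to 1), scaled by \code{library_size}.
#'
#' @param model a \code{decipher_model}.
#' @param v_points numeric matrix (points x dim_v).
#' @param library_size positive scalar scale of the output.
#' @return List with \code{expression} (points x genes), \code{mu}
#'   (normalized means), and the intermediate \code{z}.
#' @export
decipher_decode <- function(model, v_points, library_size = 1) {
  stopifnot(inherits(model, "decipher_model"))
  if (!is.matrix(v_points)) v_points <- matrix(v_points, ncol = model$config$dim_v)
  stopifnot(all(is.finite(v_points)), ncol(v_points) == model$config$dim_v)
  fo <- split_moments(mlp_forward(model$decoder_f, v_points, train = FALSE)$out)
  mu <- decode_h(model, fo$mean)
  list(expression = mu * library_size, mu = mu, z = fo$mean)
}

#' Decode with model uncertainty bands
#'
#' For each point v, draws \code{n_samples} latent factors
#' \code{z ~ N(f_mean(v), f_var(v))}, decodes each to normalized expression,
#' and returns the elementwise 25th/50th/75th percentiles across samples.
#'
#' @inheritParams decipher_decode
#' @param n_samples number of z samples per point (default 100).
#' @param seed integer seed.
#' @return List of matrices \code{q25}, \code{q50}, \code{q75}
#'   (points x genes), scaled by \code{library_size}.
#' @export
decipher_decode_uncertainty <- function(model, v_points, n_samples = 100L,
                                        library_size = 1, seed = 0L) {
  stopifnot(inherits(model, "decipher_model"), n_samples >= 2)
  if (!is.matrix(v_points)) v_points <- matrix(v_points, ncol = model$config$dim_v)
  set.seed(seed)
  M <- nrow(v_points); G <- length(model$gene_ids); L <- model$config$dim_z
  fo <- split_moments(mlp_forward(model$decoder_f, v_points, train = FALSE)$out)
  sdz <- sqrt(fo$var)
  draws <- array(NA_real_, c(n_samples, M, G))
  for (s in seq_len(n_samples)) {
    zs <- fo$mean + sdz * matrix(rnorm(M * L), M, L)
    draws[s, , ] <- decode_h(model, zs)
  }
  qs <- apply(draws, c(2, 3), stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  list(q25 = qs[1, , ] * library_size,
       q50 = qs[2, , ] * library_size,
       q75 = qs[3, , ] * library_size)
}

# Forward + (optionally) backward pass of the single-sample reparameterized
# ELBO on a minibatch. Returns the ELBO value and, when grad = TRUE, gradients
# for every parameter (as a named list matching decipher_gather_params) plus
# the updated networks (BatchNorm running statistics move in training mode).
# eps_z / eps_v may be supplied for deterministic gradient checking.
decipher_batch <- function(model, x, lib, train = TRUE, grad = TRUE,
                           eps_z = NULL, eps_v = NULL) {
  n <- nrow(x); G <- ncol(x)
  L <- model$config$dim_z; dv <- model$config$dim_v
  beta <- model$config$beta
  xlog <- log1p(x)

  ez <- mlp_forward(model$encoder_z, xlog, train = train)
  model$encoder_z <- ez$net
  qz <- split_moments(ez$out)
  if (is.null(eps_z)) eps_z <- matrix(rnorm(n * L), n, L)
  s_z <- sqrt(qz$var)
  z <- qz$mean + s_z * eps_z

  ev_in <- cbind(xlog, z)
  ev <- mlp_forward(model$encoder_v, ev_in, train = train)
  model$encoder_v <- ev$net
  qv <- split_moments(ev$out)
  if (is.null(eps_v)) eps_v <- matrix(rnorm(n * dv), n, dv)
  s_v <- sqrt(qv$var)
  v <- qv$mean + s_v * eps_v

  ff <- mlp_forward(model$decoder_f, v, train = train)
  model$decoder_f <- ff$net
  pf <- split_moments(ff$out)

  a <- sweep(z %*% model$decoder_h$W, 2, model$decoder_h$b, "+")
  mu <- row_softmax(a)
  mean_x <- sweep(mu, 1, lib, "*")
  theta <- exp(model$log_theta)
  th <- matrix(theta, n, G, byrow = TRUE)

  ll_nb <- sum(lgamma(x + th) - lgamma(th) - lgamma(x + 1) +
               th * (log(th) - log(th + mean_x)) +
               x * (log(mean_x) - log(th + mean_x)))
  lp_zv <- -0.5 * sum(log(2 * pi * pf$var) + (z - pf$mean)^2 / pf$var)
  lq_z <- -0.5 * sum(log(2 * pi * qz$var)) - 0.5 * sum(eps_z^2)
  lp_v <- -0.5 * sum(log(2 * pi) + v^2)
  lq_v <- -0.5 * sum(log(2 * pi * qv$var)) - 0.5 * sum(eps_v^2)
  elbo <- ll_nb + lp_zv - lq_z + beta * (lp_v - lq_v)

  if (!grad) return(list(elbo = elbo, model = model, z = z, v = v))

  # ---- backward (gradients of the ELBO; caller negates for minimization) ----
  gnb <- nb_grad(x, mean_x, theta)
  dmu <- sweep(gnb$dmean, 1, lib, "*")
  da <- mu * (dmu - rowSums(dmu * mu))
  d_hW <- crossprod(z, da)
  d_hb <- colSums(da)
  dz <- tcrossprod(da, model$decoder_h$W)

  # log p(z | v)
  resid <- (z - pf$mean) / pf$var
  dz <- dz - resid
  df_mean <- resid
  df_var <- 0.5 * ((z - pf$mean)^2 / pf$var^2 - 1 / pf$var)
  df_raw <- df_var * sigmoid(pf$raw)
  fbk <- mlp_backward(model$decoder_f, ff$cache, cbind(df_mean, df_raw))
  dv_total <- fbk$dX - beta * v

  dm_v <- dv_total
  dvar_v <- (dv_total * eps_v) * (0.5 / s_v) + 0.5 * beta / qv$var
  dr_v <- dvar_v * sigmoid(qv$raw)
  evbk <- mlp_backward(model$encoder_v, ev$cache, cbind(dm_v, dr_v))
  dz <- dz + evbk$dX[, G + seq_len(L), drop = FALSE]

  dm_z <- dz
  dvar_z <- (dz * eps_z) * (0.5 / s_z) + 0.5 / qz$var
  dr_z <- dvar_z * sigmoid(qz$raw)
  ezbk <- mlp_backward(model$encoder_z, ez$cache, cbind(dm_z, dr_z))

  grads <- c(
    prefix_names(mlp_grads_as_params(model$encoder_z, ezbk$grads), "encz."),
    prefix_names(mlp_grads_as_params(model$encoder_v, evbk$grads), "encv."),
    prefix_names(mlp_grads_as_params(model$decoder_f, fbk$grads), "f."),
    list(h.W = d_hW, h.b = d_hb, log_theta = gnb$dlog_theta))
  list(elbo = elbo, grads = grads, model = model)
}

prefix_names <- function(x, prefix) {
  names(x) <- paste0(prefix, names(x))
  x
}

decipher_gather_params <- function(model) {
  c(prefix_names(mlp_get_params(model$encoder_z), "encz."),
    prefix_names(mlp_get_params(model$encoder_v), "encv."),
    prefix_names(mlp_get_params(model$decoder_f), "f."),
    list(h.W = model$decoder_h$W, h.b = model$decoder_h$b,
         log_theta = model$log_theta))
}

decipher_scatter_params <- function(model, params) {
  strip <- function(prefix) {
    sel <- startsWith(names(params), prefix)
    out <- params[sel]
    names(out) <- substring(names(out), nchar(prefix) + 1)
    out
  }
  model$encoder_z <- mlp_set_params(model$encoder_z, strip("encz."))
  model$encoder_v <- mlp_set_params(model$encoder_v, strip("encv."))
  model$decoder_f <- mlp_set_params(model$decoder_f, strip("f."))
  model$decoder_h$W <- params$h.W
  model$decoder_h$b <- params$h.b
  model$log_theta <- params$log_theta
  model
}

#' Monte-Carlo ELBO estimate for a batch of cells
#'
#' Diagnostic evidence-lower-bound estimate using reparameterized samples:
#' z is drawn from q(z|x) first, then v from q(v|z,x). Each cell's noise is
#' drawn from the same \code{seed}, so the estimate is invariant to the
#' ordering of cells and additive over concatenated batches.
#'
#' @param model a \code{decipher_model}.
#' @param counts a \code{\link{count_matrix}} (gene set must match the model).
#' @param n_mc_samples number of Monte-Carlo samples per cell.
#' @param seed integer seed for the per-cell noise.
#' @return The ELBO estimate (a scalar; sum over cells).
#' @export
decipher_elbo <- function(model, counts, n_mc_samples = 1L, seed = 0L) {
  stopifnot(inherits(model, "decipher_model"), n_mc_samples >= 1)
  x <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (nrow(x) == 0) stop("batch is empty")
  if (ncol(x) != length(model$gene_ids)) stop("gene set does not match the model")
  lib <- rowSums(x)
  L <- model$config$dim_z; dv <- model$config$dim_v
  total <- 0
  for (i in seq_len(nrow(x))) {
    # the same per-cell seed makes the estimate order-invariant and additive
    set.seed(seed)
    eps_z <- matrix(rnorm(n_mc_samples * L), n_mc_samples, L)
    eps_v <- matrix(rnorm(n_mc_samples * dv), n_mc_samples, dv)
    xi <- x[rep(i, n_mc_samples), , drop = FALSE]
    r <- decipher_batch(model, xi, rep(lib[i], n_mc_samples), train = FALSE,
                        grad = FALSE, eps_z = eps_z, eps_v = eps_v)
    total <- total + r$elbo / n_mc_samples
  }
  total
}

#' Importance-sampling estimate of the log marginal likelihood
#'
#' Independent oracle for checking that the ELBO is a lower bound: estimates
#' log p(x) per cell by averaging the likelihood over samples from the prior
#' p(v) p(z|v). Only practical for tiny models.
#'
#' @inheritParams decipher_elbo
#' @param n_samples number of prior samples.
#' @return Sum over cells of the estimated log evidence.
#' @export
decipher_log_evidence <- function(model, counts, n_samples = 1e5, seed = 0L) {
  x <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  lib <- rowSums(x)
  set.seed(seed)
  dv <- model$config$dim_v; L <- model$config$dim_z
  v <- matrix(rnorm(n_samples * dv), n_samples, dv)
  fo <- split_moments(mlp_forward(model$decoder_f, v, train = FALSE)$out)
  z <- fo$mean + sqrt(fo$var) * matrix(rnorm(n_samples * L), n_samples, L)
  mu <- decode_h(model, z)
  theta <- exp(model$log_theta)
  total <- 0
  for (i in seq_len(nrow(x))) {
    m <- sweep(mu, 1, lib[i], "*")
    ll <- rowSums(matrix(stats::dnbinom(rep(x[i, ], each = n_samples),
                                        size = rep(theta, each = n_samples),
                                        mu = as.vector(m), log = TRUE),
                         n_samples, ncol(x)))
    mx <- max(ll)
    total <- total + mx + log(mean(exp(ll - mx)))
  }
  total
}
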