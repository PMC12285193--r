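# Minimal multilayer-perceptron machinery: dense layers, optional BatchNorm on
# hidden layers, ReLU/tanh activations, manual reverse-mode gradients, and Adam.
# Everything operates on plain numeric matrices (rows = observations) and draws
# initial weights from the current R RNG stream so callers control seeding.

#' @keywords internal
softplus <- function(x) {
  # log(1 + exp(x)) computed without overflow
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Create an MLP.
#
# dims: integer vector of layer widths, e.g. c(10, 64, 20) is 10 -> 64 -> 20.
# The final layer is always affine (no activation, no BatchNorm).
# activation: "relu" or "tanh", applied after each hidden layer.
# batchnorm: apply BatchNorm after each hidden affine layer (before activation).
# init_sd: "he" (sqrt(2/fan_in)), "fan_in" (sqrt(1/fan_in)).
mlp_new <- function(dims, activation = "relu", batchnorm = FALSE,
                    init_sd = "he", bias_init = TRUE) {
  stopifnot(length(dims) >= 2)
  n_layers <- length(dims) - 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- dims[l]
    sd <- switch(init_sd,
                 he = sqrt(2 / fan_in),
                 fan_in = sqrt(1 / fan_in),
                 stop("unknown init_sd"))
    W <- matrix(rnorm(fan_in * dims[l + 1], sd = sd), fan_in, dims[l + 1])
    b <- if (bias_init && init_sd == "fan_in") {
      rnorm(dims[l + 1], sd = sd)
    } else {
      numeric(dims[l + 1])
    }
    hidden <- l < n_layers
    bn <- NULL
    if (batchnorm && hidden) {
      bn <- list(gamma = rep(1, dims[l + 1]), beta = numeric(dims[l + 1]),
                 run_mean = numeric(dims[l + 1]), run_var = rep(1, dims[l + 1]))
    }
    layers[[l]] <- list(W = W, b = b, bn = bn,
                        act = if (hidden) activation else "linear")
  }
  structure(list(layers = layers, dims = dims), class = "decipher_mlp")
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# Forward pass. Returns list(out, cache, net) — net is returned because running
# BatchNorm statistics are updated in training mode.
mlp_forward <- function(net, X, train = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  caches <- vector("list", length(net$layers))
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    cache <- list(X = A)
    Z <- A %*% ly$W
    Z <- sweep(Z, 2, ly$b, "+")
    if (!is.null(ly$bn)) {
      if (train && nrow(Z) > 1) {
        mu <- colMeans(Z)
        va <- colMeans(sweep(Z, 2, mu)^2)
        net$layers[[l]]$bn$run_mean <-
          (1 - .bn_momentum) * ly$bn$run_mean + .bn_momentum * mu
        net$layers[[l]]$bn$run_var <-
          (1 - .bn_momentum) * ly$bn$run_var + .bn_momentum * va
      } else {
        mu <- ly$bn$run_mean
        va <- ly$bn$run_var
      }
      inv_sd <- 1 / sqrt(va + .bn_eps)
      Zc <- sweep(Z, 2, mu)
      Zhat <- sweep(Zc, 2, inv_sd, "*")
      cache$Zc <- Zc
      cache$Zhat <- Zhat
      cache$inv_sd <- inv_sd
      cache$bn_train <- train && nrow(Z) > 1
      Z <- sweep(sweep(Zhat, 2, ly$bn$gamma, "*"), 2, ly$bn$beta, "+")
    }
    cache$pre_act <- Z
    A <- switch(ly$act,
                relu = pmax(Z, 0),
                tanh = tanh(Z),
                linear = Z)
    caches[[l]] <- cache
  }
  list(out = A, cache = caches, net = net)
}

# Backward pass. dOut is the gradient of the loss w.r.t. the forward output.
# Returns list(grads, dX); grads mirrors net$layers with W, b (and gamma, beta).
mlp_backward <- function(net, cache, dOut) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  dA <- dOut
  for (l in rev(seq_len(n_layers))) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    dZ <- switch(ly$act,
                 relu = dA * (cc$pre_act > 0),
                 tanh = dA * (1 - tanh(cc$pre_act)^2),
                 linear = dA)
    g <- list()
    if (!is.null(ly$bn)) {
      g$gamma <- colSums(dZ * cc$Zhat)
      g$beta <- colSums(dZ)
      dZhat <- sweep(dZ, 2, ly$bn$gamma, "*")
      if (isTRUE(cc$bn_train)) {
        n <- nrow(dZhat)
        # standard BatchNorm backward through batch statistics
        dvar <- colSums(dZhat * cc$Zc) * (-0.5) * cc$inv_sd^3
        dmu <- colSums(sweep(dZhat, 2, -cc$inv_sd, "*")) +
          dvar * colMeans(-2 * cc$Zc)
        dZ <- sweep(dZhat, 2, cc$inv_sd, "*") +
          sweep(cc$Zc, 2, 2 * dvar / n, "*") +
          matrix(dmu / n, n, length(dmu), byrow = TRUE)
      } else {
        dZ <- sweep(dZhat, 2, cc$inv_sd, "*")
      }
    }
    g$W <- crossprod(cc$X, dZ)
    g$b <- colSums(dZ)
    grads[[l]] <- g
    dA <- tcrossprod(dZ, ly$W)
  }
  list(grads = grads, dX = dA)
}

# --- flat parameter access (used by Adam and by tests' finite differences) ---

mlp_get_params <- function(net) {
  out <- list()
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    out[[paste0("W", l)]] <- ly$W
    out[[paste0("b", l)]] <- ly$b
    if (!is.null(ly$bn)) {
      out[[paste0("gamma", l)]] <- ly$bn$gamma
      out[[paste0("beta", l)]] <- ly$bn$beta
    }
  }
  out
}

mlp_set_params <- function(net, params) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- params[[paste0("W", l)]]
    net$layers[[l]]$b <- params[[paste0("b", l)]]
    if (!is.null(net$layers[[l]]$bn)) {
      net$layers[[l]]$bn$gamma <- params[[paste0("gamma", l)]]
      net$layers[[l]]$bn$beta <- params[[paste0("beta", l)]]
    }
  }
  net
}

mlp_grads_as_params <- function(net, grads) {
  out <- list()
  for (l in seq_along(grads)) {
    g <- grads[[l]]
    out[[paste0("W", l)]] <- g$W
    out[[paste0("b", l)]] <- g$b
    if (!is.null(net$layers[[l]]$bn)) {
      out[[paste0("gamma", l)]] <- g$gamma
      out[[paste0("beta", l)]] <- g$beta
    }
  }
  out
}

# --- Adam optimizer over a named list of numeric arrays ---

adam_new <- function(params, lr = 5e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# Minimizes: params <- params - step(grads). Returns list(params, state).
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}
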