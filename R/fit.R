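#' Fit the hierarchical model by stochastic variational inference
#'
#' Trains the two-level generative model (2D top components v, latent
#' factors z, negative-binomial counts) on raw counts by maximizing the
#' beta-weighted evidence lower bound with reparameterized gradients, Adam
#' updates, and minibatches. With \code{early_stopping} a random held-out
#' fraction of cells controls termination and the best-scoring parameters
#' are kept. All randomness (initialization, shuffling, reparameterization
#' noise, validation split) is governed by \code{config$seed}.
#'
#' @param data a \code{\link{count_matrix}} of raw counts.
#' @param config a \code{\link{decipher_config}}.
#' @param verbose print per-epoch losses.
#' @return An object of classes \code{decipher_fit} and
#'   \code{decipher_model}: the trained generative parameters (v-to-z
#'   decoder, linear softmax decoder, per-gene dispersions) and encoders,
#'   plus a \code{training_log} data frame (epoch, train_loss, val_loss;
#'   losses are negative ELBO per cell).
#' @seealso \code{\link{decipher_encode}}, \code{\link{decipher_decode}},
#'   \code{\link{decipher_generate}}, \code{\link{rotate_space}}
#' @export
decipher <- function(data, config = decipher_config(), verbose = FALSE) {
  stopifnot(inherits(data, "count_matrix"), inherits(config, "decipher_config"))
  x_all <- data$counts
  N <- nrow(x_all); G <- ncol(x_all)
  zero_cells <- which(data$library_sizes == 0)
  if (length(zero_cells) > 0) {
    stop("cells with zero library size: ",
         paste(utils::head(data$cell_ids[zero_cells], 10), collapse = ", "))
  }
  if (!(config$dim_v <= config$dim_z && config$dim_z < G)) {
    stop("need dim_v <= dim_z < G")
  }

  set.seed(config$seed)
  model <- decipher_model_init(G, config)
  model$gene_ids <- data$gene_ids
  params <- decipher_gather_params(model)
  opt <- adam_new(params, lr = config$learning_rate)

  if (config$early_stopping && N >= 20) {
    n_val <- max(1L, round(config$validation_fraction * N))
    val_idx <- sample.int(N, n_val)
    train_idx <- setdiff(seq_len(N), val_idx)
  } else {
    val_idx <- integer(0)
    train_idx <- seq_len(N)
  }
  lib_all <- data$library_sizes

  log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
  best_val <- Inf; best_params <- NULL; best_bn <- NULL; stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot_elbo <- 0
    for (bi in splits) {
      xb <- x_all[bi, , drop = FALSE]
      r <- decipher_batch(model, xb, lib_all[bi], train = TRUE, grad = TRUE)
      model <- r$model  # BatchNorm running stats
      tot_elbo <- tot_elbo + r$elbo
      grads <- lapply(r$grads, function(g) -g / length(bi))
      st <- adam_step(params, grads, opt)
      params <- st$params; opt <- st$state
      model <- decipher_scatter_params(model, params)
    }
    train_loss <- -tot_elbo / length(train_idx)
    val_loss <- NA_real_
    if (length(val_idx) > 0) {
      rv <- decipher_batch(model, x_all[val_idx, , drop = FALSE],
                           lib_all[val_idx], train = FALSE, grad = FALSE)
      val_loss <- -rv$elbo / length(val_idx)
    }
    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, train_loss)
    log_val <- c(log_val, val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    }
    if (config$early_stopping && length(val_idx) > 0) {
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss
        best_params <- params
        best_bn <- model[c("encoder_z", "encoder_v", "decoder_f")]
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }
  if (!is.null(best_params)) {
    model[c("encoder_z", "encoder_v", "decoder_f")] <- best_bn
    model <- decipher_scatter_params(model, best_params)
  }
  model$training_log <- data.frame(epoch = log_epoch, train_loss = log_train,
                                   val_loss = log_val)
  class(model) <- c("decipher_fit", "decipher_model")
  model
}

#' Compute the embedding of cells under a fitted model
#'
#' Posterior expected values from the encoders, as in any autoencoder:
#' \code{z_i} is the mean of \code{q(z|x_i)} and \code{v_i} the mean of
#' \code{q(v|z_i, x_i)} evaluated at that z. Networks run in evaluation
#' mode. The gene set of \code{data} must match the model exactly (use
#' \code{\link{reindex_genes}} to align first).
#'
#' @param model a fitted \code{decipher_model}.
#' @param data a \code{\link{count_matrix}}.
#' @return An object of class \code{decipher_embedding}: \code{v}
#'   (cells x dim_v), \code{z} (cells x dim_z), \code{transform} (orthogonal
#'   dim_v x dim_v matrix already applied to v; identity here),
#'   \code{cell_ids}, and the cell \code{annotations} carried over.
#' @export
decipher_encode <- function(model, data) {
  stopifnot(inherits(model, "decipher_model"), inherits(data, "count_matrix"))
  if (!identical(data$gene_ids, model$gene_ids)) {
    extra <- setdiff(data$gene_ids, model$gene_ids)
    missing <- setdiff(model$gene_ids, data$gene_ids)
    stop("gene set mismatch; missing from data: ",
         paste(utils::head(missing, 5), collapse = ", "),
         "; not in model: ", paste(utils::head(extra, 5), collapse = ", "),
         if (length(missing) == 0 && length(extra) == 0) " (order differs)" else "")
  }
  xlog <- log1p(data$counts)
  qz <- split_moments(mlp_forward(model$encoder_z, xlog, train = FALSE)$out)
  qv <- split_moments(mlp_forward(model$encoder_v, cbind(xlog, qz$mean),
                                  train = FALSE)$out)
  structure(list(v = qv$mean, z = qz$mean,
                 transform = diag(model$config$dim_v),
                 cell_ids = data$cell_ids,
                 annotations = data$annotations),
            class = "decipher_embedding")
}

#' @export
print.decipher_embedding <- function(x, ...) {
  cat(sprintf("decipher_embedding: %d cells, v in %dD, z in %dD\n",
              nrow(x$v), ncol(x$v), ncol(x$z)))
  invisible(x)
}

#' @export
print.decipher_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Hierarchical count model: %d genes, dim_v = %d, dim_z = %d, beta = %g\n",
              length(x$gene_ids), cfg$dim_v, cfg$dim_z, cfg$beta))
  tl <- x$training_log
  cat(sprintf("Trained %d epochs; final loss (neg. ELBO/cell): %.4f\n",
              nrow(tl), tl$train_loss[nrow(tl)]))
  invisible(x)
}

#' @export
summary.decipher_fit <- function(object, ...) {
  tl <- object$training_log
  out <- list(config = object$config,
              n_genes = length(object$gene_ids),
              epochs = nrow(tl),
              final_train_loss = tl$train_loss[nrow(tl)],
              best_val_loss = if (all(is.na(tl$val_loss))) NA_real_
                              else min(tl$val_loss, na.rm = TRUE),
              dispersion_summary = summary(exp(object$log_theta)))
  class(out) <- "summary.decipher_fit"
  out
}

#' @export
print.summary.decipher_fit <- function(x, ...) {
  print(x$config)
  cat(sprintf("genes: %d   epochs: %d   final train loss: %.4f\n",
              x$n_genes, x$epochs, x$final_train_loss))
  if (!is.na(x$best_val_loss)) {
    cat(sprintf("best validation loss: %.4f\n", x$best_val_loss))
  }
  cat("per-gene dispersions theta:\n")
  print(x$dispersion_summary)
  invisible(x)
}

#' Predict method: embed cells or reconstruct expected expression
#'
#' \code{type = "latent"} returns the embedding (v and z posterior means);
#' \code{type = "response"} returns expected expression per cell, the
#' decoded normalized means scaled by each cell's library size.
#'
#' @param object a \code{decipher_fit}.
#' @param newdata a \code{\link{count_matrix}}; gene set must match.
#' @param type "latent" or "response".
#' @param ... unused.
#' @export
predict.decipher_fit <- function(object, newdata, type = c("latent", "response"),
                                 ...) {
  type <- match.arg(type)
  emb <- decipher_encode(object, newdata)
  if (type == "latent") return(emb)
  mu <- decode_h(object, emb$z)
  sweep(mu, 1, newdata$library_sizes, "*")
}

#' Simulate method: draw synthetic cells from the fitted generative model
#'
#' @param object a \code{decipher_fit}.
#' @param nsim number of cells.
#' @param seed integer seed.
#' @param library_sizes per-cell library sizes (recycled).
#' @param ... unused.
#' @return See \code{\link{decipher_generate}}.
#' @export
simulate.decipher_fit <- function(object, nsim = 1, seed = 0L,
                                  library_sizes = 2000, ...) {
  decipher_generate(object, n_cells = nsim, library_sizes = library_sizes,
                    seed = seed)
}

#' Plot method: scatter of the 2D top components
#'
#' @param x a \code{decipher_embedding}.
#' @param color_by optional annotation column name used to color cells.
#' @param ... passed to \code{plot}.
#' @export
plot.decipher_embedding <- function(x, color_by = NULL, ...) {
  col <- "grey30"
  if (!is.null(color_by) && !is.null(x$annotations)) {
    f <- as.factor(x$annotations[[color_by]])
    col <- grDevices::hcl.colors(nlevels(f), "Dark 3")[as.integer(f)]
  }
  graphics::plot(x$v[, 1], x$v[, 2], col = col, pch = 16, cex = 0.5,
                 xlab = "component 1", ylab = "component 2", ...)
  invisible(x)
}
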