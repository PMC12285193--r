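#' Model configuration
#'
#' Collects every tunable of the hierarchical generative model and its
#' stochastic variational inference. Defaults follow the settings used for
#' the model's single-cell analyses: a 2D top space, 10 latent factors, one
#' hidden layer of 64 units for the v-to-z decoder, one hidden layer of 128
#' units for each encoder, a linear softmax decoder from z to genes, prior
#' weight beta = 0.1, minibatches of 64 cells, and Adam.
#'
#' @param dim_z dimension of the latent factors z (default 10).
#' @param dim_v dimension of the top components v (default 2).
#' @param hidden_v_to_z hidden layer widths of the decoder f: v -> z (default 64).
#' @param hidden_x_to_z hidden layer widths of the encoder x -> z (default 128).
#' @param hidden_xz_to_v hidden layer widths of the encoder (x, z) -> v
#'   (default 128).
#' @param beta weight of the prior term on v in the ELBO, in [0, 1]
#'   (default 0.1).
#' @param batch_size minibatch size for stochastic variational inference
#'   (default 64).
#' @param learning_rate Adam learning rate (default 5e-3).
#' @param max_epochs maximum number of training epochs (default 100).
#' @param early_stopping use a held-out validation split to stop training.
#' @param patience early-stopping patience, in epochs (default 5).
#' @param validation_fraction held-out fraction for early stopping
#'   (default 0.1).
#' @param seed integer seed governing all randomness of a fit.
#' @return An object of class \code{decipher_config}.
#' @export
decipher_config <- function(dim_z = 10L, dim_v = 2L,
                            hidden_v_to_z = 64L,
                            hidden_x_to_z = 128L,
                            hidden_xz_to_v = 128L,
                            beta = 0.1,
                            batch_size = 64L,
                            learning_rate = 5e-3,
                            max_epochs = 100L,
                            early_stopping = TRUE,
                            patience = 5L,
                            validation_fraction = 0.1,
                            seed = 0L) {
  stopifnot(dim_z >= 1, dim_v >= 1, beta >= 0, beta <= 1,
            batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            patience >= 1, validation_fraction > 0, validation_fraction < 1)
  if (dim_v > dim_z) stop("dim_v must not exceed dim_z")
  structure(list(dim_z = as.integer(dim_z), dim_v = as.integer(dim_v),
                 hidden_v_to_z = as.integer(hidden_v_to_z),
                 hidden_x_to_z = as.integer(hidden_x_to_z),
                 hidden_xz_to_v = as.integer(hidden_xz_to_v),
                 beta = beta, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stopping = isTRUE(early_stopping),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "decipher_config")
}

#' @export
print.decipher_config <- function(x, ...) {
  cat("decipher_config\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Write or read a plain-text key = value configuration file
#'
#' A flat TOML-dialect file mirroring \code{\link{decipher_config}}: one
#' \code{key = value} pair per line, \code{#} comments, booleans as
#' true/false. Round-trips losslessly.
#'
#' @param config a \code{decipher_config}.
#' @param path file path.
#' @return \code{read_config} returns a \code{decipher_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "decipher_config"))
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v)) format(v, digits = 17)
    else as.character(v)
  }
  lines <- vapply(names(config),
                  function(nm) paste0(nm, " = ", paste(fmt(config[[nm]]), collapse = ", ")),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- if (all(vals %in% c("true", "false"))) {
      vals == "true"
    } else {
      suppressWarnings(as.numeric(vals))
    }
    if (anyNA(parsed)) parsed <- vals
    out[[key]] <- parsed
  }
  do.call(decipher_config, out)
}
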