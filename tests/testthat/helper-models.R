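# Shared fixtures, all generated in code.

# A minimal configuration for fast training in unit tests.
tiny_config <- function(...) {
  base <- list(dim_z = 3L, dim_v = 2L, hidden_v_to_z = 8L,
               hidden_x_to_z = 16L, hidden_xz_to_v = 16L,
               batch_size = 32L, max_epochs = 3L,
               early_stopping = FALSE, seed = 1L)
  do.call(decipher_config, utils::modifyList(base, list(...)))
}

# A small untrained model with reproducible weights.
tiny_model <- function(G = 12L, config = tiny_config(), seed = 99L) {
  set.seed(seed)
  decipher:::decipher_model_init(G, config)
}

# A generating model whose ground truth is identifiable: the v-to-z decoder
# is made near-deterministic (f_var ~ 0.01) and the dispersions moderate,
# so the latent geometry is recoverable from the counts in principle.
reference_recovery_model <- function(G = 200L, config = decipher_config(seed = 11L),
                                     seed = 7L) {
  set.seed(seed)
  model <- decipher:::decipher_model_init(G, config)
  nl <- length(model$decoder_f$layers)
  L <- config$dim_z
  model$decoder_f$layers[[nl]]$W[, L + seq_len(L)] <- 0
  model$decoder_f$layers[[nl]]$b[L + seq_len(L)] <- -4.6  # f_var ~ 0.01
  model$log_theta <- rep(log(5), G)
  model
}

# Draw rows of a symmetric Dirichlet (independent oracle for simplex draws).
rdirichlet <- function(n, K, alpha) {
  g <- matrix(stats::rgamma(n * K, alpha), n, K)
  g / rowSums(g)
}
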