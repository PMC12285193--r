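# Generative sampling, ELBO properties, encoding/decoding, and rotation.

test_that("generate is deterministic and rejects bad library sizes", {
  model <- tiny_model()
  g1 <- decipher_generate(model, 20, library_sizes = 100, seed = 5)
  g2 <- decipher_generate(model, 20, library_sizes = 100, seed = 5)
  expect_identical(g1$counts$counts, g2$counts$counts)
  expect_identical(g1$v, g2$v)
  expect_error(decipher_generate(model, 3, library_sizes = c(10, -1, 10)),
               "cell index 2")
})

test_that("huge dispersion gives Poisson-like counts (mean/variance ratio 1)", {
  model <- tiny_model()
  model$log_theta <- rep(log(1e8), length(model$gene_ids))
  g <- decipher_generate(model, 4000, library_sizes = 500, seed = 6)
  # per-gene conditional means vary across cells; compare against matched
  # Poisson draws through the variance of the residual-dispersion statistic
  mu <- g$mu * 500  # conditional NB mean given the latents
  disp <- (g$counts$counts - mu)^2 / pmax(mu, 1e-8)
  expect_equal(mean(disp), 1, tolerance = 0.05)
})

test_that("Monte-Carlo moments of generated counts match NB closed forms", {
  model <- tiny_model(G = 5)
  model$log_theta <- rep(log(3), 5)
  # fix one latent position: decode gives the exact conditional mean
  dec <- decipher_decode(model, matrix(c(0.3, -0.5), 1), library_size = 200)
  m <- dec$expression[1, 1]
  th <- 3
  set.seed(8)
  draws <- stats::rnbinom(50000, size = th, mu = m)
  v_true <- m + m^2 / th
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v_true / 50000))
})

test_that("ELBO is permutation-invariant and additive over cells", {
  model <- tiny_model()
  g <- decipher_generate(model, 3, library_sizes = 60, seed = 9)
  x <- g$counts$counts
  e0 <- decipher_elbo(model, g$counts, n_mc_samples = 20, seed = 4)
  e_perm <- decipher_elbo(model, count_matrix(x[c(2, 3, 1), ]),
                          n_mc_samples = 20, seed = 4)
  e_double <- decipher_elbo(model, count_matrix(rbind(x, x),
                                                cell_ids = paste0("c", 1:6)),
                            n_mc_samples = 20, seed = 4)
  expect_equal(e_perm, e0)
  expect_equal(e_double, 2 * e0)
  expect_error(decipher_elbo(model, g$counts, n_mc_samples = 0))
})

test_that("ELBO is bounded above by the importance-sampling log evidence", {
  set.seed(2)
  cfg <- decipher_config(dim_z = 2, dim_v = 1, hidden_v_to_z = 4,
                         hidden_x_to_z = 8, hidden_xz_to_v = 8, beta = 1)
  model <- tiny_model(G = 5, config = cfg)
  gen <- decipher_generate(model, 3, library_sizes = 50, seed = 6)
  el <- decipher_elbo(model, gen$counts, n_mc_samples = 5000, seed = 7)
  ev <- decipher_log_evidence(model, gen$counts, n_samples = 100000, seed = 8)
  expect_lt(el, ev)
})

test_that("encode returns the documented shapes and is a pointwise map", {
  model <- tiny_model(G = 15, config = decipher_config(
    dim_z = 10, dim_v = 2, hidden_v_to_z = 8, hidden_x_to_z = 16,
    hidden_xz_to_v = 16))
  g <- decipher_generate(model, 8, library_sizes = 80, seed = 10)
  emb <- decipher_encode(model, g$counts)
  expect_equal(dim(emb$v), c(8, 2))
  expect_equal(dim(emb$z), c(8, 10))
  # duplicated cells give identical rows
  x <- g$counts$counts
  dup <- count_matrix(rbind(x[1, , drop = FALSE], x[1, , drop = FALSE]),
                      cell_ids = c("a", "b"), gene_ids = model$gene_ids)
  emb2 <- decipher_encode(model, dup)
  expect_equal(emb2$v[1, ], emb2$v[2, ])
  expect_equal(emb2$z[1, ], emb2$z[2, ])
  # strict gene matching
  swapped <- count_matrix(x[, c(2, 1, 3:15)],
                          gene_ids = model$gene_ids[c(2, 1, 3:15)])
  expect_error(decipher_encode(model, swapped), "mismatch")
})

test_that("decoded normalized means are probability vectors and scale linearly", {
  model <- tiny_model()
  v <- matrix(rnorm(10), 5, 2)
  d1 <- decipher_decode(model, v, library_size = 1)
  expect_equal(rowSums(d1$mu), rep(1, 5), tolerance = 1e-6)
  expect_true(all(d1$mu > 0))
  d2 <- decipher_decode(model, v, library_size = 2)
  expect_equal(d2$expression, 2 * d1$expression)
})

test_that("softmax decoder outputs are probability vectors for arbitrary z", {
  model <- tiny_model()
  set.seed(12)
  z <- matrix(rnorm(200 * 3, sd = 5), 200, 3)
  mu <- decipher:::decode_h(model, z)
  expect_equal(rowSums(mu), rep(1, 200), tolerance = 1e-9)
  expect_true(all(mu > 0))
})

test_that("uncertainty bands are ordered, deterministic, and degenerate at zero variance", {
  model <- tiny_model()
  v <- matrix(rnorm(6), 3, 2)
  b1 <- decipher_decode_uncertainty(model, v, n_samples = 100, seed = 3)
  b2 <- decipher_decode_uncertainty(model, v, n_samples = 100, seed = 3)
  expect_identical(b1, b2)
  expect_true(all(b1$q25 <= b1$q50 + 1e-12))
  expect_true(all(b1$q50 <= b1$q75 + 1e-12))
  # force the conditional variance to (near) zero: bands collapse onto decode
  m0 <- model
  nl <- length(m0$decoder_f$layers)
  L <- m0$config$dim_z
  m0$decoder_f$layers[[nl]]$W[, L + seq_len(L)] <- 0
  m0$decoder_f$layers[[nl]]$b[L + seq_len(L)] <- -30  # var = floor 1e-4
  b0 <- decipher_decode_uncertainty(m0, v, n_samples = 50, seed = 3)
  d0 <- decipher_decode(m0, v)
  expect_equal(b0$q25, d0$expression, tolerance = 1e-2)
  expect_equal(b0$q75, d0$expression, tolerance = 1e-2)
})

test_that("rotation search finds the identity when labels already align", {
  set.seed(20)
  v <- matrix(rnorm(400), 200, 2)
  labels <- cut(v[, 1], 4, labels = c("a", "b", "c", "d"))
  emb <- structure(list(v = v, z = v, transform = diag(2),
                        cell_ids = paste0("c", 1:200),
                        annotations = data.frame(stage = labels)),
                   class = "decipher_embedding")
  out <- rotate_space(emb, list(column = "stage",
                                order = c("a", "b", "c", "d"), axis = 1))
  base_cor <- cor(as.integer(labels), v[, 1])
  expect_gte(out$alignment_score, base_cor - 1e-9)
  # orthogonality and isometry
  expect_equal(t(out$transform) %*% out$transform, diag(2), tolerance = 1e-12)
  expect_lt(max(abs(dist(out$v) - dist(v))), 1e-6)
})

test_that("rotation recovers a diagonal label gradient within one grid step", {
  set.seed(21)
  v <- matrix(rnorm(600), 300, 2)
  diag_score <- (v[, 1] + v[, 2]) / sqrt(2)
  labels <- cut(diag_score, 6, labels = paste0("s", 1:6))
  emb <- structure(list(v = v, z = v, transform = diag(2),
                        cell_ids = paste0("c", 1:300),
                        annotations = data.frame(stage = labels)),
                   class = "decipher_embedding")
  out <- rotate_space(emb, list(column = "stage",
                                order = paste0("s", 1:6), axis = 1))
  # brute-force over the same grid
  angles <- seq(0, 2 * pi, length.out = 101)[1:100]
  y <- as.integer(labels)
  best <- -Inf; best_ang <- NA
  for (ang in angles) {
    R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2, byrow = TRUE)
    for (fl in list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))) {
      vt <- v %*% t(diag(fl) %*% R)
      s <- cor(y, vt[, 1])
      if (s > best) { best <- s; best_ang <- ang }
    }
  }
  expect_equal(out$alignment_score, best, tolerance = 1e-12)
  achieved <- cor(y, out$v[, 1])
  expect_equal(achieved, best, tolerance = 1e-12)
  expect_error(rotate_space(emb, list(column = "absent", order = "x", axis = 1)),
               "not found")
})
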