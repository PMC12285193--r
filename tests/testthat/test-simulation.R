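# Fork simulator, random expression map, and the benchmark metrics.

test_that("transition density 1 removes nothing; density 0 empties the window", {
  s1 <- simulate_states(500, transition_density = 1, seed = 1)
  expect_equal(nrow(s1$true_states), 500)
  s0 <- simulate_states(500, transition_density = 0, seed = 1)
  w <- default_fork()$transition_window
  expect_false(any(s0$true_states[, 1] >= w[1] & s0$true_states[, 1] <= w[2]))
  expect_error(simulate_states(100, transition_density = 1.4), "0, 1")
  # pseudotime is exactly the first coordinate of the true state
  expect_identical(s0$pseudotime, s0$true_states[, 1])
  # determinism
  expect_identical(simulate_states(200, seed = 3)$noisy_states,
                   simulate_states(200, seed = 3)$noisy_states)
})

test_that("survivor count matches the binomial expectation", {
  n <- 20000; p <- 0.3
  fork <- default_fork()
  lens <- sapply(fork$branches, function(b)
    sum(sqrt(rowSums((b[-1, ] - b[-nrow(b), ])^2))))
  # window mass fraction: window x in [3.5, 4.5] covers arc pieces on trunk
  # (0.5 units of x) and on each arm (0.5 units of x, arc scaled by slope)
  arm_scale <- sqrt(1 + (2 / 4)^2)   # arms rise 2 over run 4
  q <- (0.5 + 0.5 * arm_scale) / lens[1]  # same for both branches
  s <- simulate_states(n, transition_density = p, seed = 5)
  expected <- n * (1 - q * (1 - p))
  se <- sqrt(n * q * (1 - p) * (1 - q * (1 - p)))
  expect_lt(abs(nrow(s$true_states) - expected), 3 * se)
})

test_that("expression map: width, determinism, and continuity", {
  states <- matrix(rnorm(40), 20, 2)
  e1 <- map_to_expression(states, seed = 2)
  expect_equal(ncol(e1), 500)
  expect_true(all(e1 >= 0))
  expect_identical(e1, map_to_expression(states, seed = 2))
  expect_false(isTRUE(all.equal(e1, map_to_expression(states, seed = 3))))
  # identical states map identically
  twice <- map_to_expression(rbind(states[1, ], states[1, ]), seed = 2)
  expect_equal(twice[1, ], twice[2, ])
  # continuity: perturbation response vanishes with the perturbation
  d1 <- max(abs(map_to_expression(states + 1e-2, d = 50, seed = 2) -
                map_to_expression(states, d = 50, seed = 2)))
  d2 <- max(abs(map_to_expression(states + 1e-5, d = 50, seed = 2) -
                map_to_expression(states, d = 50, seed = 2)))
  expect_lt(d2, d1 / 100)
})

test_that("global preservation is 1 for the identity and any scaled isometry", {
  sim <- simulate_states(1500, seed = 7)
  z <- sim$true_states
  expect_equal(global_preservation(z, z, 20, seed = 2), 1)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  lat <- 3.7 * (z %*% R %*% diag(c(1, -1)))  # rotate, reflect, scale
  expect_equal(global_preservation(z, lat, 20, seed = 2), 1)
})

test_that("anti-monotone latent distances give -1, matching a brute-force tau", {
  # 5 cluster centers on a line with distinct gaps; the latent centers are a
  # multidimensional-scaling embedding of the order-reversed distance matrix
  # (every cluster's distance ranking is exactly inverted)
  set.seed(8)
  t5 <- c(0, 2, 5, 9, 14)
  D <- abs(outer(t5, t5, "-"))
  Dp <- max(D) + 1 - D; diag(Dp) <- 0
  # setup sanity: the embedding of the reversed matrix inverts every
  # distance ranking exactly
  Drec <- as.matrix(dist(stats::cmdscale(Dp, k = 4)))
  for (i in 1:5) {
    expect_identical(order(Drec[i, -i]), rev(order(D[i, -i])))
  }
  lat_centers <- stats::cmdscale(Dp, k = 4)
  per <- 20
  z <- cbind(rep(t5, each = per), 0) + matrix(rnorm(100 * 2, sd = 1e-4), 100, 2)
  latent <- lat_centers[rep(1:5, each = per), ] +
    matrix(rnorm(100 * 4, sd = 1e-4), 100, 4)
  gp <- global_preservation(z, latent, n_clusters = 5, seed = 1)
  expect_equal(gp, -1)
  # brute-force Kendall tau on the distance-sum profiles (off-diagonal)
  cl <- { set.seed(1); stats::kmeans(z, 5, nstart = 10)$cluster }
  prof <- function(M) {
    Dm <- as.matrix(dist(M)); A <- rowsum(Dm, cl); t(rowsum(t(A), cl))
  }
  P1 <- prof(z); P2 <- prof(latent)
  taus <- sapply(1:5, function(i) {
    conc <- 0; disc <- 0
    for (a in setdiff(1:4, i)) for (b in setdiff((a + 1):5, i)) {
      s <- sign(P1[i, a] - P1[i, b]) * sign(P2[i, a] - P2[i, b])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
    (conc - disc) / choose(4, 2)
  })
  expect_equal(gp, mean(taus))
})

test_that("ordering score: collinear and equilateral geometries, and the formula", {
  latent <- cbind(c(0, 1, 2), 0)
  expect_equal(ordering_score(latent, c("A", "B", "C"), c("A", "B", "C")), 1)
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(ordering_score(eq, c("A", "B", "C"), c("A", "B", "C")), 0.5)
  expect_error(ordering_score(eq, c("A", "B", "C"), c("A", "B")), ">= 3")
  # random 4-cluster configuration vs explicit double loop
  set.seed(9)
  lat <- matrix(rnorm(80), 40, 2)
  labs <- sample(c("w", "x", "y", "z"), 40, replace = TRUE)
  o <- c("w", "x", "y", "z")
  got <- ordering_score(lat, labs, o)
  gd <- function(a, b) {
    A <- lat[labs == a, , drop = FALSE]; B <- lat[labs == b, , drop = FALSE]
    mean(as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                             nrow(A) + seq_len(nrow(B))])
  }
  num <- 0; den <- 0
  for (i1 in 1:3) for (i2 in (i1 + 1):4) {
    if (i2 - i1 == 1) den <- den + gd(o[i1], o[i2]) else num <- num + gd(o[i1], o[i2])
  }
  expect_equal(got, num / den)
  # scale invariance
  expect_equal(ordering_score(7 * lat, labs, o), got)
})

test_that("divergence score: degenerate zero, monotonicity, and the formula", {
  # all cells at one point: every distance zero
  lat0 <- matrix(0, 30, 2)
  labs <- rep(c("i1", "b1", "b2", "e2", "l2", "m2"), each = 5)
  expect_equal(divergence_score(lat0, labs, c("i1", "b1", "b2"),
                                c("e2", "l2", "m2"), c("i1", "e2")), 0)
  set.seed(10)
  lat <- matrix(rnorm(60), 30, 2)
  base <- divergence_score(lat, labs, c("i1", "b1", "b2"),
                           c("e2", "l2", "m2"), c("i1", "e2"))
  # translating one non-anchor group away increases the score
  lat2 <- lat; lat2[labs == "b2", ] <- lat2[labs == "b2", ] + 100
  expect_gt(divergence_score(lat2, labs, c("i1", "b1", "b2"),
                             c("e2", "l2", "m2"), c("i1", "e2")), base)
  # explicit double-loop oracle
  gd <- function(a, b) {
    A <- lat[labs == a, , drop = FALSE]; B <- lat[labs == b, , drop = FALSE]
    m <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      m <- m + sqrt(sum((A[i, ] - B[j, ])^2))
    }
    m / (nrow(A) * nrow(B))
  }
  oracle <- gd("b1", "l2") + gd("b1", "m2") + gd("b2", "l2") + gd("b2", "m2") -
    2 * gd("i1", "e2")
  expect_equal(base, oracle)
  expect_error(divergence_score(lat, labs, "i1", "e2", c("i1", "nope")),
               "absent")
})

test_that("mutation proportion follows m/(m+w+1e-10)", {
  expect_equal(mutation_proportion(3, 7), 0.3, tolerance = 1e-9)
  expect_equal(mutation_proportion(0, 0), 0)
  expect_equal(mutation_proportion(30, 0), 1, tolerance = 1e-10)
  expect_error(mutation_proportion(-1, 2))
})

test_that("neighborhood mutation proportion works on a labeled toy dataset", {
  set.seed(11)
  # two well-separated expression blobs; mutants populate blob 2 only
  x <- matrix(rpois(80 * 20, 3), 80, 20)
  x[41:80, 11:20] <- x[41:80, 11:20] + 200
  cm <- count_matrix(x)
  status <- c(rep("wildtype", 40), rep("mutant", 40))
  p <- neighborhood_mutation_proportion(cm, status, k = 10, n_components = 10)
  expect_gt(mean(p[41:80]), 0.95)
  expect_lt(mean(p[1:40]), 0.05)
  expect_error(neighborhood_mutation_proportion(cm, status, k = 100), "smaller")
})
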