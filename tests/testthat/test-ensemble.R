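test_that("a library of empty fragments yields empty networks", {
  vt <- vt_pair(n = 20)
  lib <- enumerate_fragments(vt, K = 0)
  s <- sample_network(lib, seed = 1)
  expect_equal(nrow(s$edges), 0L)
  ens <- build_ensemble(lib, M = 5, seed = 1)
  expect_equal(nrow(ens$edges), 0L)
})

test_that("mutually dependent variables never form a 2-cycle", {
  vt <- vt_pair(n = 40, effect = 1, noise = 0.1, p = 2)
  lib <- enumerate_fragments(vt, K = 1, top_fragments = Inf)
  ens <- build_ensemble(lib, M = 200, seed = 3)
  for (m in seq_len(200)) {
    ed <- ens$choices[m, ]
    has_ab <- length(lib$children[["x2"]][[ed[["x2"]]]]$parents) > 0
    has_ba <- length(lib$children[["x1"]][[ed[["x1"]]]]$parents) > 0
    expect_false(has_ab && has_ba)
  }
})

test_that("every sampled network passes an independent acyclicity check", {
  cfg <- sim_config(n_nodes = 6, n_samples = 30, edge_density = 0.4,
                    seed = 13)
  sim <- simulate_samples(generate_dag(cfg), cfg)
  lib <- enumerate_fragments(sim$data, K = 2)
  ens <- build_ensemble(lib, M = 50, seed = 2)
  for (m in seq_len(50)) {
    ed <- fragnet:::choices_to_edges(lib, ens$choices[m, ])
    g <- igraph::graph_from_data_frame(
      ed[c("parent", "child")], directed = TRUE,
      vertices = colnames(sim$data$continuous))
    expect_true(igraph::is_dag(g))
  }
})

test_that("2-variable edge rates match closed-form fragment odds", {
  set.seed(21)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  x[, "b"] <- 0.4 * x[, "a"] + rnorm(40, 0, 1)
  vt <- variable_table(x)
  lib <- enumerate_fragments(vt, K = 1, top_fragments = Inf)
  sc <- function(ch, j) lib$children[[ch]][[j]]$score
  # three DAGs: empty, a->b, b->a; product-of-fragments weights
  w0 <- exp(sc("a", 1) + sc("b", 1))
  wab <- exp(sc("a", 1) + sc("b", 2))
  wba <- exp(sc("a", 2) + sc("b", 1))
  p_ab <- wab / (w0 + wab + wba)
  p_ba <- wba / (w0 + wab + wba)
  M <- 1000
  ens <- build_ensemble(lib, M = M, seed = 5)
  f_of <- function(p, c) {
    i <- ens$edges$parent == p & ens$edges$child == c
    if (any(i)) ens$edges$f[i] else 0
  }
  expect_lt(abs(f_of("a", "b") - p_ab),
            3 * sqrt(p_ab * (1 - p_ab) / M) + 0.01)
  expect_lt(abs(f_of("b", "a") - p_ba),
            3 * sqrt(p_ba * (1 - p_ba) / M) + 0.01)
})

test_that("frequencies normalize, reproduce, and degenerate cleanly at M=1", {
  cfg <- sim_config(n_nodes = 5, n_samples = 30, edge_density = 0.4,
                    seed = 17)
  sim <- simulate_samples(generate_dag(cfg), cfg)
  lib <- enumerate_fragments(sim$data, K = 2)
  ens1 <- build_ensemble(lib, M = 100, seed = 9)
  ens2 <- build_ensemble(lib, M = 100, seed = 9)
  expect_identical(ens1$choices, ens2$choices)
  expect_identical(ens1$edges, ens2$edges)

  # per-child fragment frequencies sum to one
  sums <- tapply(ens1$fragments$f, ens1$fragments$child, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)

  m1 <- build_ensemble(lib, M = 1, seed = 4)
  expect_true(all(m1$edges$f %in% c(0, 1)))

  # frequencies bounded and counts bounded by M
  expect_true(all(ens1$edges$f >= 0 & ens1$edges$f <= 1))
  expect_true(all(ens1$edges$count <= 100))
})

test_that("exhaustive enumeration visits the known DAG counts", {
  set.seed(30)
  mk <- function(p) variable_table(
    matrix(rnorm(20 * p), 20, p, dimnames = list(NULL, paste0("v", 1:p))))
  expect_equal(attr(exact_edge_posterior(
    enumerate_fragments(mk(1), K = 0, top_fragments = Inf)), "n_dags"), 1L)
  expect_equal(attr(exact_edge_posterior(
    enumerate_fragments(mk(3), K = 2, top_fragments = Inf)), "n_dags"), 25L)
  expect_equal(attr(exact_edge_posterior(
    enumerate_fragments(mk(4), K = 3, top_fragments = Inf)), "n_dags"), 543L)
  big <- mk(6)
  expect_error(exact_edge_posterior(
    enumerate_fragments(big, K = 1, top_fragments = Inf)), "refused")
})

test_that("sampled frequencies track the exhaustive posterior", {
  for (s in 1:3) {
    cfg <- sim_config(n_nodes = 4, n_samples = 30, edge_density = 0.3,
                      fraction_conditional = 0, seed = s)
    sim <- simulate_samples(generate_dag(cfg), cfg)
    lib <- enumerate_fragments(sim$data, K = 3, top_fragments = Inf)
    po <- exact_edge_posterior(lib)
    ens <- build_ensemble(lib, M = 1000, seed = 50 + s)
    m <- merge(po, ens$edges[c("parent", "child", "f")], all = TRUE)
    m$f[is.na(m$f)] <- 0
    m$posterior[is.na(m$posterior)] <- 0
    expect_lte(max(abs(m$f - m$posterior)), 0.05)
  }
})

test_that("forward simulation reproduces the implied Gaussian moments", {
  # strong chain x1 -> x2 -> x3 so one network dominates
  set.seed(8)
  n <- 60
  x1 <- rnorm(n)
  x2 <- 1.2 * x1 + rnorm(n, 0, 0.4)
  x3 <- -0.8 * x2 + rnorm(n, 0, 0.4)
  vt <- variable_table(cbind(x1 = x1, x2 = x2, x3 = x3))
  lib <- enumerate_fragments(vt, K = 1, top_fragments = Inf)
  ens <- build_ensemble(lib, M = 1, seed = 2)

  # closed-form implied covariance: Sigma = (I - B)^-T D (I - B)^-1
  vars <- colnames(vt$continuous)
  B <- matrix(0, 3, 3, dimnames = list(vars, vars))
  D <- matrix(0, 3, 3)
  mu <- setNames(numeric(3), vars)
  ed <- fragnet:::choices_to_edges(lib, ens$choices[1, ])
  for (ci in seq_along(vars)) {
    f <- lib$children[[ci]][[ens$choices[1, ci]]]
    D[ci, ci] <- f$sigma2
    for (p in f$parents) B[p, ci] <- f$coef[[p]]
  }
  A <- solve(diag(3) - B)
  Sigma <- t(A) %*% D %*% A
  # implied means from intercepts propagated through the chain
  for (v in fragnet:::topological_order(vars, ed)) {
    f <- lib$children[[match(v, vars)]][[ens$choices[1, match(v, vars)]]]
    mu[v] <- f$coef[["(Intercept)"]] +
      sum(vapply(f$parents, function(p) f$coef[[p]] * mu[p], 0))
  }

  sim <- simulate_from_ensemble(ens, n_draws = 5000, seed = 31)
  emp <- cov(sim$continuous)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((Sigma[i, i] * Sigma[j, j] + Sigma[i, j]^2) / 5000)
    expect_lt(abs(emp[i, j] - Sigma[i, j]), 3 * se + 0.01)
  }
  expect_equal(unname(colMeans(sim$continuous)), unname(mu),
               tolerance = 0.1)
})

test_that("an empty ensemble simulates independent Gaussians at fitted means", {
  vt <- vt_pair(n = 40)
  lib <- enumerate_fragments(vt, K = 0)
  ens <- build_ensemble(lib, M = 1, seed = 1)
  sim <- simulate_from_ensemble(ens, n_draws = 4000, seed = 7)
  expect_equal(unname(colMeans(sim$continuous)),
               unname(colMeans(vt$continuous)), tolerance = 0.1)
  cc <- cor(sim$continuous)
  expect_true(all(abs(cc[upper.tri(cc)]) < 3 / sqrt(4000) + 0.02))
})
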