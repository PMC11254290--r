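test_that("propagation matches the closed form on a 2-node edge", {
  g <- ppi_graph(data.frame(u = "a", v = "b", weight = 1))
  W <- normalize_symmetric(g)
  f <- propagate(W, c(1, 0))$scores
  # (1 - a)(I - aW)^{-1} e1 with a = 0.8, hand-inverted 2x2
  expect_equal(unname(f), c(0.5556, 0.4444), tolerance = 1e-3)
  expect_equal(unname(propagate(W, c(0, 0))$scores), c(0, 0))
})

test_that("iterative and direct solvers agree on random connected graphs", {
  for (s in 1:20) {
    n <- sample(10:50, 1)
    g <- er_connected(n, 0.2, seed = 100 + s)
    W <- normalize_symmetric(g)
    p <- as.numeric(seq_len(n) %in% sample(n, 3))
    fi <- propagate(W, p, propagation_config(solver = "iterative"))$scores
    fd <- propagate(W, p, propagation_config(solver = "direct"))$scores
    expect_lt(max(abs(fi - fd)), 1e-6)
  }
})

test_that("conservation laws hold for both normalizations", {
  g <- er_connected(30, 0.15, seed = 9)
  p <- as.numeric(seq_len(30) %in% c(2, 7, 19))
  cfg <- propagation_config(solver = "direct")

  Wc <- normalize_column(g)
  expect_lt(abs(sum(propagate(Wc, p, cfg)$scores) - sum(p)), 1e-10)

  Ws <- normalize_symmetric(g)
  v <- sqrt(weighted_degrees(g))
  f <- propagate(Ws, p, cfg)$scores
  expect_lt(abs(sum(v * f) - sum(v * p)), 1e-10)
})

test_that("propagation is monotone in the prior support", {
  g <- er_connected(25, 0.2, seed = 5)
  W <- normalize_symmetric(g)
  f1 <- propagate(W, as.numeric(seq_len(25) %in% c(1, 4)))$scores
  f2 <- propagate(W, as.numeric(seq_len(25) %in% c(1, 4, 11)))$scores
  expect_true(all(f2 >= f1 - 1e-12))
})

test_that("non-convergence raises an informative error", {
  g <- er_connected(20, 0.2, seed = 2)
  W <- normalize_symmetric(g)
  expect_error(
    propagate(W, rep(1, 20), propagation_config(max_iterations = 2L)),
    "converge")
})

test_that("per-source scores equal naive per-source propagation", {
  g <- er_connected(30, 0.15, seed = 31)
  W <- normalize_symmetric(g)
  sources <- g$nodes[c(1, 5, 12, 20)]
  targets <- g$nodes[c(3, 5, 28)]
  S <- per_source_scores(W, sources, targets)
  for (ci in seq_along(sources)) {
    f <- propagate(W, as.numeric(g$nodes == sources[ci]),
                   propagation_config(solver = "direct"))$scores
    expect_equal(unname(S[ci, ]), unname(f[targets]), tolerance = 1e-8)
  }
  # symmetric walk matrix: F_c(u) = F_u(c)
  S2 <- per_source_scores(W, targets, sources)
  expect_equal(unname(S), unname(t(S2)), tolerance = 1e-10)
  expect_error(per_source_scores(W, "nope", targets), "nope")
})

test_that("score fields are additive over single-source priors", {
  g <- er_connected(30, 0.15, seed = 77)
  W <- normalize_symmetric(g)
  seeds <- c(2, 9, 17)
  cfg <- propagation_config(solver = "direct")
  fsum <- Reduce(`+`, lapply(seeds, function(s)
    propagate(W, as.numeric(seq_len(30) == s), cfg)$scores))
  fset <- propagate(W, as.numeric(seq_len(30) %in% seeds), cfg)$scores
  expect_equal(fset, fsum, tolerance = 1e-10)
})
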