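ring_with_hub <- function() {
  # hub "h" touching 20 leaves, leaves chained so the graph is connected
  leaves <- sprintf("l%02d", 1:20)
  ppi_graph(rbind(
    data.frame(u = "h", v = leaves, weight = 1),
    data.frame(u = leaves[-20], v = leaves[-1], weight = 1)))
}

test_that("benchmark preprocessing balances degree directions and drops conflicts", {
  g <- ring_with_hub()
  leaves <- sprintf("l%02d", 1:20)
  raw <- rbind(
    data.frame(u = "h", v = leaves[1:10], source = "s1"),      # high -> low
    data.frame(u = leaves[11:16], v = "h", source = "s1"),     # low -> high
    data.frame(u = "l01", v = "l02", source = "s1"),           # conflict a->b
    data.frame(u = "l02", v = "l01", source = "s2"),           # conflict b->a
    data.frame(u = "offnet", v = "h", source = "s1"))          # off-network
  b <- preprocess_benchmark(raw, g, seed = 3)
  r <- attr(b, "report")
  expect_equal(r$n_off_network, 1L)
  expect_equal(r$n_conflicting, 1L)
  deg <- weighted_degrees(g)
  hi2lo <- sum(deg[b$u] > deg[b$v])
  lo2hi <- sum(deg[b$u] < deg[b$v])
  expect_equal(hi2lo, 6L)
  expect_equal(lo2hi, 6L)
  expect_false(any(b$u == "l01" & b$v == "l02"))

  # idempotent: preprocessing its own output changes nothing
  b2 <- preprocess_benchmark(b, g, seed = 99)
  expect_equal(b2$u, b$u)
  expect_equal(b2$v, b$v)

  # equal-degree endpoints are kept unconditionally
  tie <- data.frame(u = "l05", v = "l06", source = "s1")  # equal degree 3
  bt <- preprocess_benchmark(rbind(raw, tie), g, seed = 3)
  expect_true(any(bt$u == "l05" & bt$v == "l06"))
  expect_equal(attr(bt, "report")$n_degree_ties, 1L)
})

test_that("PR and ROC metrics agree with hand-worked and oracle values", {
  m <- pr_metrics(c(.9, .8, .3, .1), c(1, 0, 1, 0))
  expect_equal(m$auroc, 0.75)
  expect_equal(m$auprc, (1 + 2 / 3) / 2)

  p <- pr_metrics(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))
  expect_equal(p$auprc, 1.0)
  expect_equal(p$auroc, 1.0)

  set.seed(10)
  s <- runif(4000); y <- rbinom(4000, 1, 0.5)
  r <- pr_metrics(s, y)
  expect_equal(r$auroc, 0.5, tolerance = 0.05)
  expect_equal(r$auprc, mean(y), tolerance = 0.05)

  expect_error(pr_metrics(c(1, 2), c(1, 1)), "positive and")

  # independent oracle for the rank AUROC
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- rnorm(60); y <- rbinom(60, 1, 0.4)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s, direction = "<"))))
  expect_equal(pr_metrics(s, y)$auroc, ref, tolerance = 1e-10)
})

test_that("AUPRC matches an exhaustive threshold-sweep oracle on small inputs", {
  set.seed(13)
  for (rep in 1:5) {
    s <- round(runif(15), 2); y <- rbinom(15, 1, 0.5)
    if (sum(y) %in% c(0, 15)) next
    # oracle: precision at each positive's rank under descending order
    ord <- order(-s, -y)
    ys <- y[ord]
    ap <- mean(cumsum(ys)[ys == 1] / seq_along(ys)[ys == 1])
    expect_equal(pr_metrics(s, y)$auprc, ap)
  }
})

test_that("complex-edge depletion follows its defining ratio", {
  set.seed(14)
  edges <- data.frame(u = sprintf("p%03d", 1:100), v = sprintf("q%03d", 1:100))
  cx <- edges[1:20, ]                       # 20% of edges are complex edges
  # scores that place exactly one complex edge in the top 20
  s <- c(rep(1, 5), runif(95, 0, 0.5))
  s[1:20] <- c(1, runif(19, 0, 0.4))        # complex edge 1 is in the top
  top <- order(-abs(s))[1:20]
  frac_top <- mean(top %in% 1:20)
  expect_equal(complex_depletion(edges, s, cx, K = 20), 0.2 / frac_top)
  expect_equal(complex_depletion(edges, s, cx, K = 100), 1.0)
  suppressMessages(
    expect_identical(complex_depletion(edges, c(rep(0.1, 20), rep(5, 80)),
                                       cx, K = 10), Inf))

  # independence between scores and the class gives depletion near 1
  reps <- replicate(20, {
    complex_depletion(edges, rnorm(100), cx, K = 50)
  })
  expect_equal(mean(reps), 1, tolerance = 0.25)
})
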