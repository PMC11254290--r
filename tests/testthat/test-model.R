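test_that("block scores are bit-identical under set permutations", {
  tf <- tiny_feats()
  feats <- tf$feats
  set.seed(21)
  model <- deeporient_init(length(feats$pair_ids),
                           deeporient_hp(phi_dims = c(16, 8),
                                         rho_dims = c(8), z = 4))
  for (trial in 1:100) {
    e <- sample(nrow(feats$edges), 1)
    pr <- sample(length(feats$pair_ids), 1)
    cp <- edge_couples(feats, e, pr)
    s0 <- block_score(model, cp, pr)
    cp2 <- list(cause = cp$cause[sample(nrow(cp$cause)), , drop = FALSE],
                effect = cp$effect[sample(nrow(cp$effect)), , drop = FALSE])
    expect_identical(block_score(model, cp2, pr), s0)
    expect_gt(s0, 0); expect_lt(s0, 1)
  }
})

test_that("mean aggregation: singletons pass through and duplication is a no-op", {
  tf <- tiny_feats()
  feats <- tf$feats
  set.seed(22)
  model <- deeporient_init(length(feats$pair_ids),
                           deeporient_hp(phi_dims = c(8), rho_dims = c(6), z = 2))
  cp <- edge_couples(feats, 2L, 1L)
  one <- list(cause = cp$cause[1, , drop = FALSE],
              effect = cp$effect[1, , drop = FALSE])
  dup <- list(cause = rbind(one$cause, one$cause),
              effect = rbind(one$effect, one$effect))
  expect_equal(block_score(model, dup, 1L), block_score(model, one, 1L),
               tolerance = 1e-12)
  dup2 <- list(cause = rbind(cp$cause, cp$cause),
               effect = rbind(cp$effect, cp$effect))
  expect_equal(block_score(model, dup2, 1L), block_score(model, cp, 1L),
               tolerance = 1e-12)
})

test_that("the two orientation probabilities are exactly complementary", {
  tf <- tiny_feats()
  feats <- tf$feats
  set.seed(23)
  model <- deeporient_init(length(feats$pair_ids), deeporient_hp())
  out <- deeporient_forward(model, feats, 1:10)
  expect_true(all(out$f > 0 & out$f < 1))

  rev_edges <- tf$feats$edges[1:10, c("v", "u")]
  featsR <- assemble_features(tf$world$observed_graph, tf$world$pairs,
                              rev_edges, scale = feats$scale)
  outR <- deeporient_forward(model, featsR)
  expect_equal(outR$f, 1 - out$f, tolerance = 1e-12)
  expect_equal(out$S, outR$S_rev, tolerance = 1e-12)

  # zero final layer: every edge is a coin toss
  model$params$w[] <- 0
  model$params$b <- 0
  expect_identical(unique(deeporient_forward(model, feats, 1:5)$f), 0.5)

  bad <- deeporient_init(length(feats$pair_ids) + 1L, deeporient_hp())
  expect_error(deeporient_forward(bad, feats), "embeddings")
})

test_that("the composite loss matches hand-computed values", {
  expect_equal(deeporient_loss(0.5, matrix(0.5, 1, 4), 1, beta = 0.5), log(2))
  # beta = 1 reduces to plain BCE on the final output
  expect_equal(deeporient_loss(0.9, matrix(0.1, 1, 3), 1, beta = 1), -log(0.9))
  # perfect predictions give (numerically) zero loss
  expect_lt(deeporient_loss(c(1, 0), rbind(rep(1, 4), rep(0, 4)), c(1, 0), 0.5),
            1e-6)
  # probabilities are clamped before the log, so exact 0/1 are finite
  expect_true(is.finite(deeporient_loss(0, matrix(1, 1, 2), 1, beta = 0.7)))
  expect_error(deeporient_loss(0.5, matrix(0.5, 1, 2), 1, beta = 2))
})

test_that("backpropagated gradients match finite differences", {
  tf <- tiny_feats()
  feats <- tf$feats
  hp <- deeporient_hp(phi_dims = c(6, 4), rho_dims = c(5), z = 3,
                      beta = 0.5)
  set.seed(1)
  model <- deeporient_init(length(feats$pair_ids), hp)
  U <- feats$ui[1:4]; V <- feats$vi[1:4]; y <- c(1, 0, 1, 0)
  lg <- netorient:::model_loss_grads(model$params, feats, U, V, y, hp,
                                     training = FALSE)
  v0 <- unlist(model$params, use.names = FALSE)
  g_an <- unlist(lg$grads, use.names = FALSE)
  set.seed(2)
  idx <- sample(length(v0), 50)
  for (i in idx) {
    e <- 1e-5
    vp <- v0; vp[i] <- vp[i] + e
    vm <- v0; vm[i] <- vm[i] - e
    lp <- netorient:::model_loss_grads(utils::relist(vp, model$params), feats,
                                       U, V, y, hp, training = FALSE)$loss
    lm <- netorient:::model_loss_grads(utils::relist(vm, model$params), feats,
                                       U, V, y, hp, training = FALSE)$loss
    g_num <- (lp - lm) / (2 * e)
    expect_equal(g_an[i], g_num, tolerance = 1e-4)
  }
})

test_that("each pair's embedding only influences its own block", {
  tf <- tiny_feats()
  feats <- tf$feats
  set.seed(31)
  model <- deeporient_init(length(feats$pair_ids),
                           deeporient_hp(phi_dims = c(8), rho_dims = c(6), z = 4))
  base <- deeporient_forward(model, feats, 1:6)$S
  k <- 3L
  model$params$emb[k, ] <- model$params$emb[k, ] + 0.5
  pert <- deeporient_forward(model, feats, 1:6)$S
  expect_false(isTRUE(all.equal(base[, k], pert[, k])))
  expect_identical(base[, -k], pert[, -k])
})
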