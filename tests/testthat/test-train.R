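test_that("sampled configurations stay inside the search space", {
  space <- hp_search_space()
  set.seed(1)
  draws <- replicate(40, sample_hp(space), simplify = FALSE)
  for (hp in draws) {
    expect_true(hp$dropout %in% c(0, 0.2, 0.4, 0.7))
    expect_true(hp$beta %in% c(0.25, 0.5, 0.75, 0.9, 0.99))
    expect_true(hp$z %in% c(4L, 8L, 12L, 16L, 20L))
    expect_true(hp$learning_rate %in% c(5e-5, 1e-4, 5e-4, 1e-3, 5e-3))
    expect_true(any(vapply(space$phi_dims, identical, TRUE, hp$phi_dims)))
    expect_true(any(vapply(space$rho_dims, identical, TRUE, hp$rho_dims)))
  }
  set.seed(7); a <- replicate(10, sample_hp(space), simplify = FALSE)
  set.seed(7); b <- replicate(10, sample_hp(space), simplify = FALSE)
  expect_identical(a, b)  # fixed seed, identical sequence
})

test_that("splits are disjoint, covering, and stratified", {
  bench <- data.frame(u = sprintf("a%03d", 1:60), v = sprintf("b%03d", 1:60),
                      source = rep(c("s1", "s2", "s3"), each = 20))
  sp <- split_benchmark(bench, c(0.7, 0.15, 0.15), seed = 3)
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_idx, 1:60)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  for (s in unique(bench$source))
    expect_gt(length(intersect(sp$train, which(bench$source == s))), 0L)
  expect_identical(split_benchmark(bench, seed = 3), sp)  # deterministic
})

test_that("training reduces the loss and early stopping respects patience", {
  tf <- tiny_feats()
  feats <- tf$feats
  sp <- split_benchmark(tf$bench, seed = 2)
  hp <- deeporient_hp(phi_dims = c(16, 8), rho_dims = c(8), z = 4,
                      learning_rate = 5e-3)
  m <- fit_deeporient(feats, sp$train, sp$val, hp, restarts = 1L,
                      patience = 3L, max_epochs = 12L, seed = 5)
  h <- m$history
  expect_lt(mean(tail(h$train_loss, 3)), h$train_loss[1])
  expect_gte(m$val_auprc, max(h$val_auprc))

  # patience 0 stops at the first epoch without validation improvement
  m0 <- fit_deeporient(feats, sp$train, sp$val, hp, restarts = 1L,
                       patience = 0L, max_epochs = 50L, seed = 5)
  h0 <- m0$history
  cm <- cummax(h0$val_auprc)
  first_bad <- which(h0$val_auprc[-1] <= cm[-length(cm)])[1]
  if (!is.na(first_bad)) expect_equal(max(h0$epoch), first_bad + 1L)

  expect_error(fit_deeporient(feats, integer(0), sp$val, hp), "empty")
})

test_that("random search returns the best-validated configuration", {
  tf <- tiny_feats()
  feats <- tf$feats
  sp <- split_benchmark(tf$bench, seed = 2)
  space <- list(phi_dims = list(c(8L)), rho_dims = list(c(6L)),
                dropout = 0, beta = c(0.5, 0.9), z = 4L,
                learning_rate = c(1e-3, 5e-3))
  sr <- random_search(feats, sp$train, sp$val, budget = 2L, space = space,
                      seed = 9, max_epochs = 4L, patience = 1L)
  expect_equal(nrow(sr$log), 2L)
  expect_equal(sr$best_val_auprc, max(sr$log$val_auprc))
  expect_error(random_search(feats, sp$train, sp$val, budget = 0L), "budget")
})

test_that("cross-validation folds partition the benchmark", {
  tf <- tiny_feats()
  w <- tf$world
  hp <- deeporient_hp(phi_dims = c(8L), rho_dims = c(6L), z = 4L,
                      learning_rate = 5e-3)
  cv <- cross_validate(w$observed_graph, w$pairs, tf$bench, k = 2L, hp = hp,
                       seed = 3, restarts = 1L, patience = 2L, max_epochs = 5L)
  expect_equal(nrow(cv), 2L)
  expect_equal(sum(cv$n_test), nrow(tf$bench))
  expect_true(all(cv$auprc >= 0 & cv$auprc <= 1))
  expect_error(cross_validate(w$observed_graph, w$pairs, tf$bench, k = 1000L),
               "exceeds")
})

test_that("the fitted orienter object supports the standard methods", {
  tf <- tiny_feats()
  w <- tf$world
  hp <- deeporient_hp(phi_dims = c(16, 8), rho_dims = c(8), z = 4,
                      learning_rate = 5e-3)
  fit <- deeporient(w$observed_graph, w$pairs, tf$bench, hp = hp,
                    restarts = 1L, patience = 2L, max_epochs = 8L, seed = 11)
  expect_s3_class(fit, "deeporient")
  expect_output(print(fit), "AUPRC")
  expect_output(summary(fit), "Hyperparameters")
  expect_length(coef(fit), length(fit$feats$pair_ids))

  pr <- predict(fit, tf$bench[1:8, c("u", "v")])
  expect_equal(nrow(pr), 8L)
  expect_true(all(pr$f > 0 & pr$f < 1))
  # rerun with the same seed reproduces the metrics exactly
  fit2 <- deeporient(w$observed_graph, w$pairs, tf$bench, hp = hp,
                     restarts = 1L, patience = 2L, max_epochs = 8L, seed = 11)
  expect_identical(fit$metrics, fit2$metrics)

  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
})
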