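#' Hyperparameter search space
#'
#' The discrete random-search space: encoder and aggregator width lists,
#' dropout ratio, loss weight beta, embedding size and learning rate.
#' @return named list of candidate values; list-valued fields hold one
#'   entry per candidate architecture.
#' @export
hp_search_space <- function() {
  list(
    phi_dims = list(c(128L, 64L), c(64L, 32L, 16L), c(64L, 32L), c(128L, 64L, 32L)),
    rho_dims = list(c(128L, 64L), c(64L, 32L, 16L), c(64L, 32L), c(32L, 16L, 8L), c(32L, 16L)),
    dropout = c(0, 0.2, 0.4, 0.7),
    beta = c(0.25, 0.5, 0.75, 0.9, 0.99),
    z = c(4L, 8L, 12L, 16L, 20L),
    learning_rate = c(5e-5, 1e-4, 5e-4, 1e-3, 5e-3)
  )
}

#' Draw one configuration uniformly from a search space
#' @param space a [hp_search_space()]-shaped list. Uses the current RNG.
#' @return a [deeporient_hp()].
#' @export
sample_hp <- function(space = hp_search_space()) {
  pick <- function(x) if (is.list(x)) x[[sample.int(length(x), 1L)]] else
    x[sample.int(length(x), 1L)]
  deeporient_hp(phi_dims = pick(space$phi_dims),
                rho_dims = pick(space$rho_dims),
                dropout = pick(space$dropout),
                beta = pick(space$beta),
                z = pick(space$z),
                learning_rate = pick(space$learning_rate))
}

#' Split benchmark edges into disjoint train/validation/test groups
#'
#' Splits at the level of unordered benchmark edges (each directed
#' benchmark edge later contributes its true ordering as a positive and
#' the reverse ordering as a negative, and both always land in the same
#' group, preventing leakage). Stratified by the benchmark source label
#' so rare sources stay represented in every group.
#'
#' @param bench a \code{benchmark_set} (or data frame u, v, source).
#' @param proportions length-3 nonnegative vector (train, val, test)
#'   summing to 1.
#' @param seed integer seed.
#' @return list of integer row-index vectors \code{train}, \code{val},
#'   \code{test}; a partition of \code{seq_len(nrow(bench))}.
#' @export
split_benchmark <- function(bench, proportions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(length(proportions) == 3L, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-9)
  src <- if ("source" %in% names(bench)) bench$source else rep("all", nrow(bench))
  set.seed(seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (s in unique(src)) {
    idx <- sample(which(src == s))
    n <- length(idx)
    n_tr <- round(proportions[1] * n)
    n_va <- round(proportions[2] * n)
    n_va <- min(n_va, n - n_tr)
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$val <- c(out$val, idx[n_tr + seq_len(n_va)])
    out$test <- c(out$test, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  lapply(out, sort)
}

# Metrics over both ordered predictions of each benchmark edge: the
# stored (u, v) ordering is the positive, the reverse the negative
# (whose probability is exactly 1 - f).
eval_split <- function(model, feats, idx) {
  out <- deeporient_forward(model, feats, idx)
  pr_metrics(c(out$f, 1 - out$f), rep(c(1, 0), each = length(idx)))
}

#' Train the orienter with restarts and early stopping
#'
#' Trains \code{restarts} differently initialized models with Adam on
#' mini-batches of ordered edge samples; each run stops after
#' \code{patience} consecutive epochs without improvement of validation
#' AUPRC (the best-epoch weights are kept) and the restart with the best
#' validation AUPRC is returned.
#'
#' @param feats features over the benchmark edges ([assemble_features()]).
#' @param train_idx,val_idx disjoint benchmark row indices.
#' @param hp a [deeporient_hp()].
#' @param restarts number of independent initializations.
#' @param patience early-stopping patience in epochs (0 stops at the
#'   first non-improving epoch).
#' @param max_epochs hard epoch cap.
#' @param batch_size mini-batch size in ordered samples.
#' @param seed integer seed; restart r uses \code{seed + r}.
#' @return a \code{deeporient_model} with attached \code{val_auprc} and
#'   \code{history} (per-restart data frame of epoch, train_loss,
#'   val_auprc).
#' @export
fit_deeporient <- function(feats, train_idx, val_idx, hp = deeporient_hp(),
                           restarts = 3L, patience = 5L, max_epochs = 100L,
                           batch_size = 64L, seed = 1L) {
  if (!length(train_idx) || !length(val_idx))
    stop("empty train or validation set")
  N <- length(feats$pair_ids)
  # one training sample per benchmark edge; each contributes both ordered
  # predictions inside model_loss_grads
  trU <- feats$ui[train_idx]; trV <- feats$vi[train_idx]
  n_tr <- length(train_idx)
  best_model <- NULL
  best_val <- -Inf
  history <- list()

  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    model <- deeporient_init(N, hp)
    state <- adam_init(model$params)
    run_best <- -Inf
    run_params <- model$params
    bad <- 0L
    hist_r <- NULL
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_tr)
      tot <- 0
      for (start in seq(1L, n_tr, by = batch_size)) {
        b <- ord[start:min(start + batch_size - 1L, n_tr)]
        lg <- model_loss_grads(model$params, feats, trU[b], trV[b],
                               rep(1, length(b)), hp, training = TRUE)
        upd <- adam_step(model$params, lg$grads, state, hp$learning_rate)
        model$params <- upd$params
        state <- upd$state
        tot <- tot + lg$loss * length(b)
      }
      vm <- eval_split(model, feats, val_idx)
      hist_r <- rbind(hist_r, data.frame(restart = r, epoch = epoch,
                                         train_loss = tot / n_tr,
                                         val_auprc = vm$auprc))
      if (vm$auprc > run_best) {
        run_best <- vm$auprc
        run_params <- model$params
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= max(1L, patience)) break
      }
    }
    history[[r]] <- hist_r
    if (run_best > best_val) {
      best_val <- run_best
      model$params <- run_params
      best_model <- model
    }
  }
  best_model$val_auprc <- best_val
  best_model$history <- do.call(rbind, history)
  best_model
}

#' Random hyperparameter search
#'
#' Samples \code{budget} configurations from the search space, trains
#' each (single restart) and returns the configuration with the best
#' validation AUPRC together with the full search log.
#'
#' @param feats,train_idx,val_idx as in [fit_deeporient()].
#' @param budget number of sampled configurations (>= 1).
#' @param space search space, see [hp_search_space()].
#' @param seed integer seed controlling both the sampled sequence and
#'   the training runs.
#' @param max_epochs,patience,batch_size training controls per candidate.
#' @return list with \code{best_hp}, \code{best_val_auprc} and
#'   \code{log} (a data frame, one row per candidate).
#' @export
random_search <- function(feats, train_idx, val_idx, budget,
                          space = hp_search_space(), seed = 1L,
                          max_epochs = 30L, patience = 3L, batch_size = 64L) {
  if (budget < 1L) stop("search budget must be at least 1")
  set.seed(seed)
  hps <- replicate(budget, sample_hp(space), simplify = FALSE)
  log <- NULL
  best <- NULL; best_val <- -Inf
  for (i in seq_len(budget)) {
    hp <- hps[[i]]
    m <- fit_deeporient(feats, train_idx, val_idx, hp, restarts = 1L,
                        patience = patience, max_epochs = max_epochs,
                        batch_size = batch_size, seed = seed * 1000L + i)
    log <- rbind(log, data.frame(
      candidate = i,
      phi_dims = paste(hp$phi_dims, collapse = "-"),
      rho_dims = paste(hp$rho_dims, collapse = "-"),
      dropout = hp$dropout, beta = hp$beta, z = hp$z,
      learning_rate = hp$learning_rate, val_auprc = m$val_auprc))
    if (m$val_auprc > best_val) { best_val <- m$val_auprc; best <- hp }
  }
  list(best_hp = best, best_val_auprc = best_val, log = log)
}

#' Fit a deep-set network orienter
#'
#' The main entry point: assembles diffusion-score features for the
#' benchmark edges over the undirected network, splits the benchmark into
#' train/validation/test, optionally runs a random hyperparameter search,
#' trains with restarts and early stopping, and evaluates on the held-out
#' test edges.
#'
#' @param network undirected \code{ppi_graph}.
#' @param pairs a [ce_pairs()] collection of guiding cause--effect sets
#'   (oversized sets are removed via [filter_pairs()]).
#' @param benchmark a \code{benchmark_set} (see [preprocess_benchmark()]):
#'   directed edges whose stored ordering is the true direction.
#' @param hp hyperparameters; default [deeporient_hp()] unless a search
#'   is requested.
#' @param search_budget if > 0, run [random_search()] with this budget
#'   and use the winning configuration.
#' @param proportions train/val/test proportions, see [split_benchmark()].
#' @param restarts,patience,max_epochs,batch_size see [fit_deeporient()].
#' @param config propagation settings ([propagation_config()]).
#' @param transform encoder input transform, see [assemble_features()].
#' @param max_set_size guiding-set size cap, see [filter_pairs()].
#' @param seed integer master seed.
#' @return object of class \code{deeporient} with the trained model, the
#'   split, training history and held-out metrics; see
#'   [predict.deeporient()].
#' @export
deeporient <- function(network, pairs, benchmark, hp = NULL,
                       search_budget = 0L, proportions = c(0.7, 0.15, 0.15),
                       restarts = 3L, patience = 5L, max_epochs = 100L,
                       batch_size = 64L, config = propagation_config(),
                       transform = "scaled", max_set_size = 1000L, seed = 1L) {
  pairs <- filter_pairs(pairs, max_set_size)
  if (!length(pairs)) stop("no guiding pairs left after filtering")
  W <- normalize_symmetric(network)
  feats <- assemble_features(network, pairs, benchmark[, c("u", "v")],
                             config = config, transform = transform, W = W)
  split <- split_benchmark(benchmark, proportions, seed = seed)

  search_log <- NULL
  if (is.null(hp)) {
    if (search_budget > 0L) {
      sr <- random_search(feats, split$train, split$val, search_budget,
                          seed = seed, batch_size = batch_size)
      hp <- sr$best_hp
      search_log <- sr$log
    } else hp <- deeporient_hp()
  }

  model <- fit_deeporient(feats, split$train, split$val, hp,
                          restarts = restarts, patience = patience,
                          max_epochs = max_epochs, batch_size = batch_size,
                          seed = seed)
  test_metrics <- eval_split(model, feats, split$test)

  structure(list(model = model, hp = hp, feats = feats, split = split,
                 benchmark = benchmark, network = network, pairs = pairs,
                 config = config, transform = transform,
                 history = model$history, search_log = search_log,
                 metrics = list(val_auprc = model$val_auprc,
                                test_auprc = test_metrics$auprc,
                                test_auroc = test_metrics$auroc),
                 seed = seed, call = match.call()),
            class = "deeporient")
}

#' @export
print.deeporient <- function(x, ...) {
  cat("Deep-set network orienter\n")
  cat(sprintf("  guiding pairs: %d   benchmark edges: %d (train %d / val %d / test %d)\n",
              length(x$pairs), nrow(x$benchmark),
              length(x$split$train), length(x$split$val), length(x$split$test)))
  cat(sprintf("  validation AUPRC: %.3f   test AUPRC: %.3f   test AUROC: %.3f\n",
              x$metrics$val_auprc, x$metrics$test_auprc, x$metrics$test_auroc))
  invisible(x)
}

#' @export
summary.deeporient <- function(object, ...) {
  cat("Deep-set network orienter\n\nHyperparameters:\n  ")
  print(object$hp)
  cat("\nData:\n")
  cat(sprintf("  network: %d nodes, %d edges\n",
              length(object$network$nodes), nrow(object$network$edges)))
  cat(sprintf("  guiding pairs: %d; benchmark edges: %d\n",
              length(object$pairs), nrow(object$benchmark)))
  cat(sprintf("  split: train %d / val %d / test %d (edge level; both orderings share a group)\n",
              length(object$split$train), length(object$split$val),
              length(object$split$test)))
  cat("\nHeld-out performance (positives = true orderings, negatives = reversed):\n")
  cat(sprintf("  test AUPRC: %.4f\n  test AUROC: %.4f\n",
              object$metrics$test_auprc, object$metrics$test_auroc))
  ep <- stats::aggregate(epoch ~ restart, data = object$history, FUN = max)
  cat(sprintf("\nTraining: %d restart(s), epochs per restart: %s\n",
              length(unique(object$history$restart)),
              paste(ep$epoch, collapse = ", ")))
  invisible(object)
}

#' @export
coef.deeporient <- function(object, ...) {
  w <- object$model$params$w
  names(w) <- object$feats$pair_ids
  w
}

#' Predict orientation probabilities for edges
#'
#' @param object a fitted [deeporient()] object.
#' @param edges two-column data frame of candidate edges (node ids);
#'   default: every edge of the training network.
#' @param ... unused.
#' @return data frame (u, v, f) where \code{f} is the probability that
#'   the edge is directed u -> v; the reverse ordering has probability
#'   \code{1 - f}.
#' @export
predict.deeporient <- function(object, edges = NULL, ...) {
  if (is.null(edges)) edges <- object$network$edges[, c("u", "v")]
  feats <- assemble_features(object$network, object$pairs, edges,
                             config = object$config,
                             transform = object$transform,
                             scale = object$feats$scale)
  n <- nrow(feats$edges)
  f <- numeric(n)
  for (start in seq(1L, n, by = 256L)) {    # chunked to bound memory
    idx <- start:min(start + 255L, n)
    f[idx] <- deeporient_forward(object$model, feats, idx)$f
  }
  data.frame(u = feats$edges$u, v = feats$edges$v, f = f,
             stringsAsFactors = FALSE)
}

#' @export
plot.deeporient <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(NA, xlim = range(h$epoch), ylim = range(h$train_loss),
       xlab = "epoch", ylab = "training loss", main = "Loss")
  for (r in unique(h$restart))
    graphics::lines(h$epoch[h$restart == r], h$train_loss[h$restart == r],
                    col = r)
  plot(NA, xlim = range(h$epoch), ylim = c(0, 1),
       xlab = "epoch", ylab = "validation AUPRC", main = "Validation")
  for (r in unique(h$restart))
    graphics::lines(h$epoch[h$restart == r], h$val_auprc[h$restart == r],
                    col = r)
  invisible(x)
}

#' k-fold cross-validation of the orienter
#'
#' Partitions the benchmark edges into k folds (stratified by source);
#' each fold in turn is the test set while the remainder is split into
#' train and validation. When \code{search_budget > 0} the hyperparameter
#' search is repeated inside every fold.
#'
#' @param network,pairs,benchmark as in [deeporient()].
#' @param k number of folds.
#' @param search_budget per-fold random-search budget (0 = use \code{hp}).
#' @param hp hyperparameters when no search is run.
#' @param seed integer seed.
#' @param ... passed to [deeporient()]'s training controls.
#' @return data frame with one row per fold: test AUPRC/AUROC and the
#'   chosen hyperparameters.
#' @export
cross_validate <- function(network, pairs, benchmark, k = 5L,
                           search_budget = 0L, hp = deeporient_hp(),
                           seed = 1L, restarts = 1L, patience = 5L,
                           max_epochs = 100L, batch_size = 64L,
                           config = propagation_config(), transform = "scaled") {
  n <- nrow(benchmark)
  if (k > n) stop(sprintf("k = %d exceeds the %d benchmark edges", k, n))
  pairs <- filter_pairs(pairs)
  W <- normalize_symmetric(network)
  feats <- assemble_features(network, pairs, benchmark[, c("u", "v")],
                             config = config, transform = transform, W = W)
  src <- if ("source" %in% names(benchmark)) benchmark$source else rep("all", n)
  set.seed(seed)
  fold <- integer(n)
  for (s in unique(src)) {
    idx <- sample(which(src == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  res <- NULL
  for (fd in seq_len(k)) {
    test_idx <- which(fold == fd)
    rest <- which(fold != fd)
    set.seed(seed + fd)
    rest <- sample(rest)
    n_va <- max(1L, round(0.18 * length(rest)))
    val_idx <- sort(rest[seq_len(n_va)])
    train_idx <- sort(rest[-seq_len(n_va)])
    hp_fd <- hp
    if (search_budget > 0L) {
      sr <- random_search(feats, train_idx, val_idx, search_budget,
                          seed = seed + 100L * fd, batch_size = batch_size)
      hp_fd <- sr$best_hp
    }
    m <- fit_deeporient(feats, train_idx, val_idx, hp_fd, restarts = restarts,
                        patience = patience, max_epochs = max_epochs,
                        batch_size = batch_size, seed = seed + 10L * fd)
    tm <- eval_split(m, feats, test_idx)
    res <- rbind(res, data.frame(
      fold = fd, n_test = length(test_idx),
      auprc = tm$auprc, auroc = tm$auroc,
      phi_dims = paste(hp_fd$phi_dims, collapse = "-"),
      rho_dims = paste(hp_fd$rho_dims, collapse = "-"),
      dropout = hp_fd$dropout, beta = hp_fd$beta, z = hp_fd$z,
      learning_rate = hp_fd$learning_rate))
  }
  res
}
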