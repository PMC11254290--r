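#' Hyperparameters of the deep-set orienter
#'
#' Defaults are the reference configuration used throughout the package:
#' couple encoders of widths 128-64, an aggregator of widths 64-32, no
#' dropout, loss mixing weight \code{beta = 0.5}, embedding size 8 and
#' learning rate 1e-3. The first aggregator layer size is always
#' determined by twice the last encoder width plus the embedding size.
#'
#' @param phi_dims hidden widths of the two (identically shaped) per-couple
#'   encoder networks; input dimension is fixed at 2 (score at u, score at v).
#' @param rho_dims hidden widths of the aggregator network; a final linear
#'   unit producing the scalar block output is appended automatically.
#' @param dropout dropout ratio on hidden activations during training.
#' @param beta loss mixing weight in [0, 1]: \code{beta} on the final
#'   classifier BCE, \code{1 - beta} on the mean per-block BCE.
#' @param z dimension of the per-pair embedding vector.
#' @param learning_rate Adam step size.
#' @return a \code{deeporient_hp} list.
#' @export
deeporient_hp <- function(phi_dims = c(128, 64), rho_dims = c(64, 32),
                          dropout = 0, beta = 0.5, z = 8,
                          learning_rate = 1e-3) {
  stopifnot(length(phi_dims) >= 1, length(rho_dims) >= 1,
            dropout >= 0, dropout < 1, beta >= 0, beta <= 1, z >= 1,
            learning_rate > 0)
  structure(list(phi_dims = as.integer(phi_dims),
                 rho_dims = as.integer(rho_dims),
                 dropout = dropout, beta = beta, z = as.integer(z),
                 learning_rate = learning_rate),
            class = "deeporient_hp")
}

#' @export
print.deeporient_hp <- function(x, ...) {
  cat(sprintf("deeporient_hp: phi [%s], rho [%s], dropout %g, beta %g, z %d, lr %g\n",
              paste(x$phi_dims, collapse = ","), paste(x$rho_dims, collapse = ","),
              x$dropout, x$beta, x$z, x$learning_rate))
  invisible(x)
}

#' Initialize an untrained deep-set orienter
#'
#' Weight layout: two per-couple encoders (identical architecture,
#' separate weights) applied to cause and effect score couples; a shared
#' aggregator mapping [mean cause encoding || mean effect encoding ||
#' pair embedding] to a scalar squashed to (0, 1); one embedding vector
#' per guiding pair; and a final linear layer mapping the N block scores
#' to an orientation logit. The logit is evaluated on both edge orderings
#' and softmaxed, so f(u->v) + f(v->u) = 1 by construction.
#'
#' All layers use uniform fan-in initialization; embeddings are
#' zero-mean Gaussian with scale 0.1. Uses the current RNG state.
#'
#' @param n_pairs number of guiding pairs N (embedding-table size).
#' @param hp a [deeporient_hp()].
#' @return object of class \code{deeporient_model}.
#' @export
deeporient_init <- function(n_pairs, hp = deeporient_hp()) {
  h <- hp$phi_dims[length(hp$phi_dims)]
  params <- list(
    phiC = mlp_init(c(2L, hp$phi_dims)),
    phiE = mlp_init(c(2L, hp$phi_dims)),
    rho  = mlp_init(c(2L * h + hp$z, hp$rho_dims, 1L)),
    emb  = matrix(stats::rnorm(n_pairs * hp$z, sd = 0.1), n_pairs, hp$z),
    w    = stats::runif(n_pairs, -1 / sqrt(n_pairs), 1 / sqrt(n_pairs)),
    b    = 0
  )
  structure(list(params = params, hp = hp, n_pairs = as.integer(n_pairs)),
            class = "deeporient_model")
}

#' @export
print.deeporient_model <- function(x, ...) {
  np <- sum(unlist(tree_map(length, x$params)))
  cat(sprintf("deeporient_model: %d guiding pairs, %d parameters\n",
              x$n_pairs, np))
  print(x$hp)
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean-pool grid-evaluated encoder outputs into a (B*N) x h matrix ordered
# sample-major, pair-minor. P is the sparse (N x S) per-pair averaging
# operator; G holds encoder outputs on the (source x edge) grid, rows
# ordered edge-major, source-minor. Implemented as one sparse-dense
# product via reshaping.
pool_means <- function(P, G, B) {
  S <- ncol(P); N <- nrow(P); h <- ncol(G)
  PG <- as.matrix(P %*% matrix(as.vector(G), S, B * h))
  matrix(as.vector(PG), N * B, h)
}

# Adjoint of pool_means: scatter pooled gradients back onto the grid.
pool_means_bwd <- function(P, dM, B) {
  S <- ncol(P); N <- nrow(P); h <- ncol(dM)
  PG <- as.matrix(Matrix::t(P) %*% matrix(as.vector(dM), N, B * h))
  matrix(as.vector(PG), S * B, h)
}

# Forward pass of the block stack for one ordering of a batch of edges.
# U, V: column indices into feats$Mt of the candidate heads/tails. The
# couple encoders are evaluated once on the (source gene x edge) grid --
# couple (Fs(u), Fs(v)) for every source s and batch edge -- and per-pair
# set means are then sparse pooling products, so shared genes across
# pairs are encoded only once.
block_stack_forward <- function(params, feats, U, V, hp, training = FALSE) {
  B <- length(U)
  N <- length(feats$pair_ids)
  Mt <- feats$Mt

  X <- cbind(as.vector(Mt[, U, drop = FALSE]),
             as.vector(Mt[, V, drop = FALSE]))   # (S*B) x 2 grid couples
  fc <- mlp_forward(params$phiC, X, hp$dropout, training)
  fe <- mlp_forward(params$phiE, X, hp$dropout, training)
  Mc <- pool_means(feats$Pc, fc$out, B)
  Me <- pool_means(feats$Pe, fe$out, B)
  Emb <- params$emb[rep.int(seq_len(N), B), , drop = FALSE]
  H <- cbind(Mc, Me, Emb)

  fr <- mlp_forward(params$rho, H, hp$dropout, training)
  t <- as.numeric(fr$out)
  s <- sigmoid(t)
  S <- t(matrix(s, N, B))            # B x N block scores
  logits <- as.numeric(S %*% params$w) + params$b

  list(S = S, s = s, logits = logits, t = t,
       fc = fc, fe = fe, fr = fr, B = B, N = N)
}

# Backward through one block stack given dt (length B*N, sample-major) at
# the pre-squash block outputs. Returns parameter gradients (final layer
# excluded; handled by the caller).
block_stack_backward <- function(params, feats, cache, dt) {
  B <- cache$B; N <- cache$N
  h <- ncol(cache$fc$out)
  br <- mlp_backward(params$rho, cache$fr$caches, matrix(dt, ncol = 1L))
  dH <- br$dX
  dMc <- dH[, seq_len(h), drop = FALSE]
  dMe <- dH[, h + seq_len(h), drop = FALSE]
  dEmb_rows <- dH[, 2L * h + seq_len(ncol(params$emb)), drop = FALSE]
  demb <- rowsum(dEmb_rows, rep.int(seq_len(N), B), reorder = TRUE)

  bc <- mlp_backward(params$phiC, cache$fc$caches, pool_means_bwd(feats$Pc, dMc, B))
  be <- mlp_backward(params$phiE, cache$fe$caches, pool_means_bwd(feats$Pe, dMe, B))

  list(phiC = bc$grads, phiE = be$grads, rho = br$grads, emb = demb)
}

#' Evaluate the orienter on a batch of candidate edges
#'
#' Runs the block stack on both orderings (u, v) and (v, u) and softmaxes
#' the two shared-final-layer logits, so that
#' \code{f(u->v) + f(v->u) = 1} exactly.
#'
#' @param model a \code{deeporient_model}.
#' @param feats an [assemble_features()] result whose pair set matches the
#'   model's embedding table.
#' @param edge_idx edge row indices (default: all edges in \code{feats}).
#' @return list with \code{f} (probability of the given u -> v ordering),
#'   \code{S} and \code{S_rev} (B x N per-block scores for each ordering).
#' @export
deeporient_forward <- function(model, feats, edge_idx = seq_len(nrow(feats$edges))) {
  if (length(feats$pair_ids) != model$n_pairs)
    stop(sprintf("feature set has %d pairs but model has %d embeddings",
                 length(feats$pair_ids), model$n_pairs))
  U <- feats$ui[edge_idx]; V <- feats$vi[edge_idx]
  fwd <- block_stack_forward(model$params, feats, U, V, model$hp)
  rev <- block_stack_forward(model$params, feats, V, U, model$hp)
  f <- sigmoid(fwd$logits - rev$logits)
  list(f = f, S = fwd$S, S_rev = rev$S,
       logits = fwd$logits, logits_rev = rev$logits)
}

#' Score of a single block on one edge and one guiding pair
#'
#' The permutation-invariant set function at the heart of the method:
#' cause couples and effect couples are encoded element-wise, mean-pooled
#' per set, concatenated with the pair's embedding and mapped to a scalar
#' in (0, 1). Couples are canonically sorted before pooling, so the score
#' is bit-identical under any permutation of either set (floating-point
#' summation order is fixed).
#'
#' @param model a \code{deeporient_model}.
#' @param couples list with matrices \code{cause} and \code{effect}
#'   (couples in rows), e.g. from [edge_couples()].
#' @param pair pair index (selects the embedding vector).
#' @return scalar block score in (0, 1).
#' @export
block_score <- function(model, couples, pair) {
  params <- model$params
  canon <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  pool <- function(layers, m) {
    if (is.null(m) || nrow(m) == 0L)
      return(numeric(ncol(mlp_forward(layers, matrix(0, 1, 2))$out)))
    colSums(mlp_forward(layers, canon(m))$out) / nrow(m)
  }
  mc <- pool(params$phiC, couples$cause)
  me <- pool(params$phiE, couples$effect)
  hvec <- c(mc, me, params$emb[pair, ])
  sigmoid(as.numeric(mlp_forward(params$rho, matrix(hvec, 1L))$out))
}

#' Composite orientation loss
#'
#' \code{beta * BCE(f, y) + (1 - beta) * mean_j BCE(score_j, y)} for a
#' single prediction; over a batch the losses are averaged. Probabilities
#' are clamped to [1e-7, 1 - 1e-7] before the logarithm.
#'
#' @param f final orientation probabilities (vector, one per prediction).
#' @param block_scores matrix of per-block scores (rows = predictions).
#' @param y true labels in {0, 1} (1 = the given ordering is the true
#'   direction).
#' @param beta mixing weight in [0, 1].
#' @return scalar mean loss.
#' @export
deeporient_loss <- function(f, block_scores, y, beta) {
  stopifnot(beta >= 0, beta <= 1)
  block_scores <- matrix(block_scores, nrow = length(f))
  per <- beta * bce(f, y) + (1 - beta) * rowMeans(bce(block_scores, y))
  mean(per)
}

# Loss + full parameter gradients for a labelled batch of benchmark edges.
# U, V index feats$Mt columns; y in {0,1} labels the stored (U, V)
# ordering. Each edge contributes BOTH ordered predictions -- (U, V) with
# label y and (V, U) with label 1 - y -- whose final-classifier BCEs
# coincide (f(v->u) = 1 - f(u->v)); the batch loss is the mean over the
# 2B ordered predictions, computed from one forward/reverse stack pair
# per edge.
model_loss_grads <- function(params, feats, U, V, y, hp, training = TRUE) {
  B <- length(U)
  N <- length(feats$pair_ids)
  fwd <- block_stack_forward(params, feats, U, V, hp, training)
  rev <- block_stack_forward(params, feats, V, U, hp, training)
  f <- sigmoid(fwd$logits - rev$logits)
  loss <- deeporient_loss(c(f, 1 - f), rbind(fwd$S, rev$S),
                          c(y, 1 - y), hp$beta)

  dl <- hp$beta * (f - y) / B                    # d loss / d logit_fwd
  # final linear layer (bias cancels in the softmax difference)
  gw <- as.numeric(crossprod(fwd$S - rev$S, dl))
  gb <- 0
  # pre-squash block gradients, sample-major pair-minor
  s_f <- fwd$s; s_r <- rev$s
  yrep <- rep(y, each = N)
  wrep <- rep.int(params$w, B)
  dlrep <- rep(dl, each = N)
  blk <- (1 - hp$beta) / (2 * N * B)
  dt_f <- dlrep * wrep * s_f * (1 - s_f) + blk * (s_f - yrep)
  dt_r <- -dlrep * wrep * s_r * (1 - s_r) + blk * (s_r - (1 - yrep))

  gf <- block_stack_backward(params, feats, fwd, dt_f)
  gr <- block_stack_backward(params, feats, rev, dt_r)
  grads <- list(
    phiC = tree_map2(`+`, gf$phiC, gr$phiC),
    phiE = tree_map2(`+`, gf$phiE, gr$phiE),
    rho  = tree_map2(`+`, gf$rho, gr$rho),
    emb  = gf$emb + gr$emb,
    w = gw, b = gb
  )
  list(loss = loss, grads = grads, f = f)
}
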