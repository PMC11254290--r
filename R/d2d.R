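#' D2D orientation ratio for one edge and one guiding pair
#'
#' The proximity-ratio baseline: with FC(x) the summed diffusion
#' proximity of node x to the cause set and FE(x) to the effect set,
#' \code{score(u->v) = (FC(u) * FE(v)) / (FC(v) * FE(u))}. Values above 1
#' favor the u -> v orientation; the reverse ordering scores the exact
#' reciprocal. A small epsilon is added to each of the four sums before
#' the ratio, since sparse priors make exact zeros common on small graphs.
#'
#' @param fc_u,fe_u,fc_v,fe_v the four nonnegative proximity sums.
#' @param eps regularizer added to each sum.
#' @return scalar ratio score.
#' @export
d2d_score <- function(fc_u, fe_u, fc_v, fe_v, eps = 1e-12) {
  stopifnot(fc_u >= 0, fe_u >= 0, fc_v >= 0, fe_v >= 0)
  if (fc_u == 0 && fe_u == 0 && fc_v == 0 && fe_v == 0)
    warning("all four proximity sums are zero; returning the epsilon-regularized ratio")
  ((fc_u + eps) * (fe_v + eps)) / ((fc_v + eps) * (fe_u + eps))
}

#' Aggregate D2D ranking score per edge
#'
#' Per guiding pair the edge gets the ratio of [d2d_score()]; ratios are
#' combined across pairs by their geometric mean (mean of logs), which
#' preserves the reciprocal antisymmetry between the two orderings.
#' Raw (untransformed) diffusion scores are used, as the ratio is
#' scale-invariant but not log-shift-invariant.
#'
#' @param feats an [assemble_features()] result.
#' @param edge_idx edge row indices (default all).
#' @param eps zero-sum guard added to each proximity sum.
#' @return numeric vector of geometric-mean ratio scores for the stored
#'   (u, v) orientation of each requested edge.
#' @export
d2d_rank_edges <- function(feats, edge_idx = seq_len(nrow(feats$edges)),
                           eps = 1e-12) {
  N <- length(feats$pair_ids)
  # per-pair proximity sums at every endpoint column: N x T
  # (pairs whose mapped set is empty keep an all-zero row)
  pair_sums <- function(idx_all, counts) {
    out <- matrix(0, N, ncol(feats$M))
    if (length(idx_all)) {
      rs <- rowsum(feats$M[idx_all, , drop = FALSE],
                   rep.int(seq_len(N), counts), reorder = TRUE)
      out[as.integer(rownames(rs)), ] <- rs
    }
    out
  }
  FC <- pair_sums(feats$cause_all, feats$cause_counts)
  FE <- pair_sums(feats$effect_all, feats$effect_counts)
  U <- feats$ui[edge_idx]; V <- feats$vi[edge_idx]
  lo <- function(m, cols) log(m[, cols, drop = FALSE] + eps)
  # N x B matrix of per-pair log ratios
  L <- lo(FC, U) + lo(FE, V) - lo(FC, V) - lo(FE, U)
  exp(colMeans(L))
}
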