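#' Consensus orientation score across a group of models
#'
#' For an edge (u, v) each model m contributes the log probability ratio
#' \code{log(fm(u->v) / fm(v->u))}; the consensus score is their sum.
#' Because every model satisfies \code{fm(u->v) + fm(v->u) = 1}, the score
#' of the reversed ordering is exactly the negation. Probabilities are
#' clamped to [1e-7, 1 - 1e-7] before the logarithm.
#'
#' @param f per-model probabilities of the u -> v ordering: a numeric
#'   vector (one edge, several models) or a matrix with one row per edge
#'   and one column per model.
#' @return numeric vector of consensus scores, one per edge.
#' @export
consensus_score <- function(f) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  f <- clamp_prob(f)
  as.numeric(rowSums(log(f / (1 - f))))
}

#' Commit top-confidence edges to hard orientations
#'
#' Edges are ranked by the magnitude of their consensus score (the sign
#' only decides which direction wins); the top \code{orient_fraction} of
#' the ranking receives a hard direction and the rest stays undirected.
#' The default leaves 20% of edges unoriented. Ties in |score| are broken
#' by lexicographic edge id so the output is deterministic.
#'
#' @param edges two-column data frame of unordered edges (u, v).
#' @param scores per-edge consensus scores for the u -> v ordering
#'   (positive favors u -> v).
#' @param orient_fraction fraction of edges to orient, in [0, 1].
#' @return data frame (u, v, score, hard_direction) where
#'   \code{hard_direction} is \code{"u>v"}, \code{"v>u"} or \code{"none"};
#'   the number of oriented edges is \code{round(orient_fraction * n)}.
#' @export
harden <- function(edges, scores, orient_fraction = 0.80) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("u", "v")
  if (nrow(edges) == 0L) stop("harden: empty edge list")
  stopifnot(length(scores) == nrow(edges),
            orient_fraction >= 0, orient_fraction <= 1)
  n <- nrow(edges)
  k <- round(orient_fraction * n)
  ord <- order(-abs(scores), edges$u, edges$v)
  hard <- rep("none", n)
  pick <- ord[seq_len(k)]
  hard[pick] <- ifelse(scores[pick] >= 0, "u>v", "v>u")
  data.frame(u = edges$u, v = edges$v, score = scores,
             hard_direction = hard, stringsAsFactors = FALSE)
}

#' Extract the oriented edge list from a hardened consensus table
#' @param hardened output of [harden()].
#' @return two-column data frame of (from, to) pairs for [orient_edges()].
#' @export
hard_directions <- function(hardened) {
  keep <- hardened$hard_direction != "none"
  data.frame(
    from = ifelse(hardened$hard_direction[keep] == "u>v",
                  hardened$u[keep], hardened$v[keep]),
    to = ifelse(hardened$hard_direction[keep] == "u>v",
                hardened$v[keep], hardened$u[keep]),
    stringsAsFactors = FALSE)
}
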