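#' Assemble per-edge diffusion-score couples for a set of guiding pairs
#'
#' For every candidate edge (u, v) and every cause--effect pair j this
#' produces the two sets of score couples the set encoder consumes:
#' cause couples \{(Fc(u), Fc(v)) : c in Cj\} and effect couples
#' \{(Fe(u), Fe(v)) : e in Ej\}, where Fc(u) is the diffusion score of u
#' when propagating from the single source c over the undirected network.
#' Scores are computed once for all (source gene, edge endpoint)
#' combinations via [per_source_scores()] and shared across edges.
#'
#' Guiding genes absent from the network are dropped per pair (counts
#' messaged); a pair whose cause and effect sets are both entirely
#' off-network is dropped with a warning.
#'
#' @param g undirected \code{ppi_graph}.
#' @param pairs a [ce_pairs()] collection (after [filter_pairs()]).
#' @param edges two-column data frame / matrix of candidate edges (node
#'   ids); couple order follows the given (u, v) orientation.
#' @param config a [propagation_config()].
#' @param transform encoder input transform. \code{"scaled"} (default)
#'   feeds raw diffusion scores divided by their mean, keeping inputs
#'   O(1) while preserving the linear structure that proximity sums rely
#'   on; \code{"log"} feeds \code{log(score + 1e-10)}; \code{"raw"}
#'   feeds untransformed scores.
#' @param scale divisor for the \code{"scaled"} transform; defaults to
#'   the mean of the computed score matrix. Pass a stored value to score
#'   new edges on the same scale a model was trained with.
#' @param W optional precomputed walk matrix (defaults to
#'   [normalize_symmetric()] of \code{g}).
#' @return object of class \code{edge_features}; see [edge_couples()] for
#'   the per-edge accessor.
#' @export
assemble_features <- function(g, pairs, edges, config = propagation_config(),
                              transform = c("scaled", "log", "raw"),
                              scale = NULL, W = NULL) {
  transform <- match.arg(transform)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  eu <- as.character(edges[[1]]); ev <- as.character(edges[[2]])
  node_index(g, c(eu, ev))  # errors on unknown endpoint

  # map guiding genes onto the network
  mapped <- lapply(pairs, function(p) {
    list(id = p$id,
         causes = intersect(p$causes, g$nodes),
         effects = intersect(p$effects, g$nodes),
         n_dropped = length(setdiff(p$causes, g$nodes)) +
                     length(setdiff(p$effects, g$nodes)))
  })
  dead <- vapply(mapped, function(p) {
    length(p$causes) == 0L && length(p$effects) == 0L
  }, TRUE)
  if (any(dead)) {
    warning(sprintf("dropped %d pair(s) with no guiding genes in the network: %s",
                    sum(dead),
                    paste(vapply(mapped[dead], `[[`, "", "id"), collapse = ", ")))
    mapped <- mapped[!dead]
  }
  if (!length(mapped)) stop("no usable cause-effect pairs")
  ndrop <- sum(vapply(mapped, `[[`, 0, "n_dropped"))
  if (ndrop > 0)
    message(sprintf("assemble_features: %d guiding genes not in the network were dropped", ndrop))

  sources <- sort(unique(unlist(lapply(mapped, function(p) c(p$causes, p$effects)))))
  targets <- sort(unique(c(eu, ev)))
  if (is.null(W)) W <- normalize_symmetric(g)
  M <- per_source_scores(W, sources, targets, config)
  if (transform == "scaled" && is.null(scale)) scale <- mean(M)
  Mt <- switch(transform,
               scaled = M / scale,
               log = log(M + 1e-10),
               raw = M)

  cause_idx <- lapply(mapped, function(p) match(p$causes, sources))
  effect_idx <- lapply(mapped, function(p) match(p$effects, sources))
  # sparse mean-pooling operators (pairs x sources), value 1/|set|
  pool_op <- function(idx) {
    n <- length(idx)
    Matrix::sparseMatrix(
      i = rep.int(seq_len(n), lengths(idx)), j = unlist(idx),
      x = rep.int(1 / pmax(lengths(idx), 1L), lengths(idx)),
      dims = c(n, length(sources)))
  }
  structure(list(
    Pc = pool_op(cause_idx), Pe = pool_op(effect_idx),
    M = M, Mt = Mt,
    sources = sources, targets = targets,
    pair_ids = vapply(mapped, `[[`, "", "id"),
    cause_idx = cause_idx, effect_idx = effect_idx,
    cause_all = unlist(cause_idx), cause_counts = lengths(cause_idx),
    effect_all = unlist(effect_idx), effect_counts = lengths(effect_idx),
    edges = data.frame(u = eu, v = ev, stringsAsFactors = FALSE),
    ui = match(eu, targets), vi = match(ev, targets),
    transform = transform, scale = scale, config = config
  ), class = "edge_features")
}

#' @export
print.edge_features <- function(x, ...) {
  cat(sprintf("edge_features: %d edges x %d pairs (%d source genes, transform = %s)\n",
              nrow(x$edges), length(x$pair_ids), length(x$sources), x$transform))
  invisible(x)
}

n_pairs <- function(feats) length(feats$pair_ids)

#' Extract the score couples of one edge under one guiding pair
#'
#' @param feats an [assemble_features()] result.
#' @param edge edge row index, or a length-2 character vector (u, v).
#' @param pair pair index.
#' @param reverse evaluate the opposite orientation (v, u): every couple's
#'   components are swapped.
#' @param transformed return encoder-space (transformed) scores rather
#'   than raw diffusion scores.
#' @return list with matrices \code{cause} and \code{effect}, one couple
#'   per row, columns (score at u, score at v).
#' @export
edge_couples <- function(feats, edge, pair, reverse = FALSE, transformed = TRUE) {
  if (is.character(edge)) {
    edge <- which(feats$edges$u == edge[1] & feats$edges$v == edge[2])
    if (length(edge) != 1L) stop("edge not found in feature set")
  }
  M <- if (transformed) feats$Mt else feats$M
  ui <- feats$ui[edge]; vi <- feats$vi[edge]
  if (reverse) { tmp <- ui; ui <- vi; vi <- tmp }
  couple <- function(idx) {
    m <- cbind(M[idx, ui], M[idx, vi])
    colnames(m) <- c("at_u", "at_v")
    m
  }
  list(cause = couple(feats$cause_idx[[pair]]),
       effect = couple(feats$effect_idx[[pair]]))
}

#' Restrict a feature object to a subset / reordering of its edges
#' @param feats an \code{edge_features} object.
#' @param idx edge row indices.
#' @return an \code{edge_features} object over \code{feats$edges[idx, ]}.
#' @export
subset_edges <- function(feats, idx) {
  feats$edges <- feats$edges[idx, , drop = FALSE]
  rownames(feats$edges) <- NULL
  feats$ui <- feats$ui[idx]
  feats$vi <- feats$vi[idx]
  feats
}
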