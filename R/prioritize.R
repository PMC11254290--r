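#' Rank genes by propagation from per-patient effect sets
#'
#' Given a (partially) oriented network whose one-way edges have already
#' been reversed with [flip_directions()] -- so that propagation from
#' downstream effect genes flows toward their upstream causes -- each
#' patient's effect set is used as a propagation prior and genes are
#' ranked by descending diffusion score. Per-patient ranks are then
#' aggregated (mean by default) into a single prioritization.
#'
#' Directed networks are normalized with the skeleton-degree convention
#' (see [normalize_column()]), which converges on any partially oriented
#' graph; fully undirected networks use the symmetric normalization, so
#' the same call compares oriented and unoriented runs. Each patient's
#' own seed (effect) genes are excluded from that patient's ranking
#' readout to avoid trivial self-recovery.
#'
#' @param g a \code{ppi_graph} (flip directions first when orienting
#'   cause-ward).
#' @param effect_sets named list of character gene vectors (one per
#'   patient), or a [ce_pairs()] collection (effect sets are used).
#' @param config a [propagation_config()].
#' @param aggregate rank aggregation statistic, \code{"mean"} or
#'   \code{"median"}.
#' @return object of class \code{prioritization}: list with \code{ranks}
#'   (genes x patients matrix, NA for a patient's seeds),
#'   \code{aggregate} (named vector, smaller = higher priority) and
#'   \code{universe}.
#' @export
rank_genes <- function(g, effect_sets, config = propagation_config(),
                       aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (inherits(effect_sets, "ce_pairs")) {
    ids <- vapply(effect_sets, `[[`, "", "id")
    effect_sets <- lapply(effect_sets, `[[`, "effects")
    names(effect_sets) <- ids
  }
  if (is.null(names(effect_sets)))
    names(effect_sets) <- paste0("patient", seq_along(effect_sets))
  W <- if (is_partially_directed(g)) normalize_column(g, degree = "skeleton")
       else normalize_symmetric(g)
  n <- length(g$nodes)
  ranks <- matrix(NA_real_, n, 0, dimnames = list(g$nodes, NULL))
  for (pid in names(effect_sets)) {
    seeds <- intersect(effect_sets[[pid]], g$nodes)
    if (!length(seeds)) {
      message(sprintf("rank_genes: patient '%s' has no effect genes in the network; skipped", pid))
      next
    }
    prior <- as.numeric(g$nodes %in% seeds)
    f <- propagate(W, prior, config)$scores
    keep <- !(g$nodes %in% seeds)
    r <- rep(NA_real_, n)
    ord <- order(-f[keep], g$nodes[keep])
    r[which(keep)[ord]] <- seq_len(sum(keep))
    ranks <- cbind(ranks, r)
    colnames(ranks)[ncol(ranks)] <- pid
  }
  if (!ncol(ranks)) stop("no patient had effect genes in the network")
  aggfun <- if (aggregate == "mean") function(x) mean(x, na.rm = TRUE)
            else function(x) stats::median(x, na.rm = TRUE)
  agg <- apply(ranks, 1L, aggfun)
  agg[is.nan(agg)] <- Inf   # genes that are seeds for every patient
  structure(list(ranks = ranks, aggregate = agg, universe = g$nodes,
                 method = aggregate),
            class = "prioritization")
}

#' @export
print.prioritization <- function(x, ...) {
  cat(sprintf("prioritization: %d genes over %d patients (%s-rank aggregation)\n",
              length(x$universe), ncol(x$ranks), x$method))
  top <- names(sort(x$aggregate))[seq_len(min(5L, length(x$aggregate)))]
  cat("  top genes:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Fold enrichment of target genes among the top-ranked percentile
#'
#' The fraction of the top K-percentile genes (by aggregate rank) that
#' belong to the target list, divided by the target fraction in the
#' whole universe. 1 is the chance level; K = 100 returns exactly 1.
#'
#' @param result a [rank_genes()] result, or a named numeric vector of
#'   aggregate ranks (smaller = better).
#' @param targets character vector of target genes (e.g. known drivers);
#'   intersected with the universe.
#' @param K top percentile in (0, 100].
#' @return fold enrichment (numeric scalar).
#' @export
fold_enrichment <- function(result, targets, K) {
  if (K <= 0) stop("K must be a positive percentile")
  stopifnot(K <= 100)
  agg <- if (inherits(result, "prioritization")) result$aggregate else result
  universe <- names(agg)
  targets <- intersect(targets, universe)
  if (!length(targets)) stop("no target gene is in the ranked universe")
  n <- length(agg)
  k <- max(1L, round(K / 100 * n))
  top <- names(sort(agg))[seq_len(k)]
  mean(top %in% targets) / (length(targets) / n)
}
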