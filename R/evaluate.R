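#' Preprocess a directed-interaction benchmark
#'
#' Three steps, mirroring standard practice for orientation benchmarks:
#' (i) edges with an endpoint outside the network are dropped; (ii) edges
#' reported with both orientations by different records ("conflicting")
#' are treated as undirected and removed, and exact duplicates are
#' deduplicated; (iii) to remove degree bias, the two degree-direction
#' classes -- edges directed high-degree to low-degree endpoint versus the
#' reverse, by weighted degree in the undirected network -- are balanced by
#' downsampling the majority class (seeded). Edges whose endpoints have
#' exactly equal degree carry no degree bias; they are excluded from the
#' balancing pools and retained unconditionally.
#'
#' @param raw data frame with columns \code{u}, \code{v} (direction
#'   u -> v) and optionally \code{source} (benchmark label).
#' @param g the \code{ppi_graph} the benchmark refers to.
#' @param seed integer seed for the downsampling draw.
#' @return a \code{benchmark_set}: data frame (u, v, source) with a
#'   \code{report} attribute of before/after counts.
#' @export
preprocess_benchmark <- function(raw, g, seed = 1L) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  names(raw)[1:2] <- c("u", "v")
  raw$u <- as.character(raw$u); raw$v <- as.character(raw$v)
  if (!"source" %in% names(raw)) raw$source <- "benchmark"
  n0 <- nrow(raw)

  on_net <- raw$u %in% g$nodes & raw$v %in% g$nodes & raw$u != raw$v
  bench <- raw[on_net, , drop = FALSE]
  n_off <- n0 - nrow(bench)

  dkey <- paste(bench$u, bench$v, sep = "\r")
  ukey <- paste(pmin(bench$u, bench$v), pmax(bench$u, bench$v), sep = "\r")
  # conflicting: the same unordered pair seen with both orientations
  both <- tapply(dkey, ukey, function(k) length(unique(k)) > 1L)
  conflict <- both[ukey]
  n_conflict <- length(unique(ukey[conflict]))
  bench <- bench[!conflict & !duplicated(dkey), , drop = FALSE]

  deg <- weighted_degrees(g)
  du <- deg[bench$u]; dv <- deg[bench$v]
  hi2lo <- which(du > dv)
  lo2hi <- which(du < dv)
  ties <- which(du == dv)
  set.seed(seed)
  m <- min(length(hi2lo), length(lo2hi))
  keep <- sort(c(ties,
                 if (length(hi2lo) > m) sample(hi2lo, m) else hi2lo,
                 if (length(lo2hi) > m) sample(lo2hi, m) else lo2hi))
  out <- bench[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- list(n_input = n0, n_off_network = n_off,
                 n_conflicting = n_conflict,
                 n_high_to_low = length(hi2lo), n_low_to_high = length(lo2hi),
                 n_degree_ties = length(ties),
                 n_balanced = m, n_output = nrow(out))
  structure(out, report = report, class = c("benchmark_set", "data.frame"))
}

#' @export
print.benchmark_set <- function(x, ...) {
  r <- attr(x, "report")
  cat(sprintf("benchmark_set: %d directed edges (from %d raw; %d off-network, %d conflicting removed; %d+%d degree-balanced, %d ties kept)\n",
              r$n_output, r$n_input, r$n_off_network, r$n_conflicting,
              r$n_balanced, r$n_balanced, r$n_degree_ties))
  invisible(x)
}

#' Precision--recall and ROC metrics
#'
#' AUPRC is computed in the average-precision style: precision evaluated
#' at each positive's rank, averaged over positives (a step-wise area, no
#' trapezoids). AUROC is the rank statistic (probability a positive
#' outscores a negative, ties counted half). Ranking ties are broken by
#' descending label so the AP value is deterministic.
#'
#' @param scores numeric ranking scores, higher = more confidently positive.
#' @param labels 0/1 labels.
#' @return list with \code{auprc}, \code{auroc} and a \code{curve} data
#'   frame of (recall, precision) points at each rank.
#' @export
pr_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels == 1L)
  if (P == 0L || P == length(labels))
    stop("pr_metrics needs at least one positive and one negative label")
  ord <- order(-scores, -labels)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / P
  auprc <- sum(prec[y == 1L]) / P
  # Mann-Whitney AUROC with ties counted half
  r <- rank(scores)
  auroc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * (length(labels) - P))
  list(auprc = auprc, auroc = auroc,
       curve = data.frame(recall = rec, precision = prec))
}

#' Fold depletion of a reference edge class among top-scoring orientations
#'
#' Protein-complex interactions are expected to be left unoriented by a
#' sound orienter; this statistic is the overall fraction of
#' reference-class (e.g. complex) edges divided by their fraction among
#' the edges whose absolute consensus score lies in the top K percentile.
#' Values above 1 mean the class is depleted among confident orientations.
#'
#' @param edges two-column data frame of unordered network edges.
#' @param scores per-edge consensus scores (signed; magnitude = confidence).
#' @param complex_edges two-column data frame of reference-class edges
#'   (order of endpoints irrelevant).
#' @param K top percentile in (0, 100].
#' @return fold depletion (possibly \code{Inf} when the top-K slice
#'   contains no reference edge; a message reports the counts).
#' @export
complex_depletion <- function(edges, scores, complex_edges, K) {
  stopifnot(K > 0, K <= 100)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  key <- function(d) paste(pmin(as.character(d[[1]]), as.character(d[[2]])),
                           pmax(as.character(d[[1]]), as.character(d[[2]])), sep = "\r")
  is_cx <- key(edges) %in% key(as.data.frame(complex_edges, stringsAsFactors = FALSE))
  n <- nrow(edges)
  k <- max(1L, round(K / 100 * n))
  top <- order(-abs(scores))[seq_len(k)]
  overall <- mean(is_cx)
  in_top <- mean(is_cx[top])
  if (in_top == 0) {
    message(sprintf("complex_depletion: 0 of %d top-%g%% edges are in the reference class (%d overall)",
                    k, K, sum(is_cx)))
    return(Inf)
  }
  overall / in_top
}
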