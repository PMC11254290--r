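#' Generate a planted-truth synthetic world
#'
#' Builds a strongly connected directed network organized as a layered
#' signaling hierarchy, erases the directions to obtain the observed
#' undirected network, and samples cause--effect gene-set pairs
#' consistent with directed reachability.
#'
#' The network is organized as \code{n_modules} parallel pathway modules,
#' each an independent layered cascade: every node receives a module
#' label and a latent depth in [0, 1] -- its level within its module's
#' hierarchy, receptor-like nodes shallow, effector/TF-like nodes deep.
#' The skeleton is a Hamiltonian cycle visiting modules in sequence and
#' each module in depth order (which guarantees strong connectivity)
#' plus preferential-attachment edges: one endpoint degree-weighted, the
#' partner degree-weighted among depth-nearby nodes of the same module
#' (kernel \code{exp(-|depth difference| / depth_bandwidth)}), so
#' interactions connect adjacent layers and hubs emerge, as in kinase
#' signaling cascades. Edges are oriented downhill within their module;
#' the few module-crossing cycle edges follow the cycle.
#'
#' Each pair draws its cause genes uniformly and its effect genes as the
#' endpoints of fixed-length directed random walks started from random
#' cause genes, so effects lie downstream of causes in the hidden true
#' direction of signal flow. A \code{noise} fraction of each effect set
#' is replaced by uniform random genes. Edge weights are Uniform(0.5, 1).
#'
#' The defaults define the package's reference study condition: 300
#' nodes, 1200 edges, 40 pairs, 5 causes and 30 effects per pair, walk
#' length 3 and noise 0.1.
#'
#' @param n_nodes,n_edges network size; \code{n_edges >= n_nodes} is
#'   required so the cycle closure fits.
#' @param n_pairs number of cause--effect pairs.
#' @param cause_size,effect_size genes per cause / effect set.
#' @param walk_length directed random-walk length from cause to effect
#'   (the difficulty knob: longer walks dilute the directional signal).
#' @param noise fraction of each effect set replaced by random genes,
#'   in [0, 1].
#' @param depth_bandwidth scale of the depth-proximity attachment
#'   kernel; smaller values give a more strictly layered network.
#' @param n_modules number of parallel pathway modules.
#' @param seed integer seed; the world is bit-reproducible given the seed.
#' @return object of class \code{synthetic_world}: list with
#'   \code{true_graph} (directed), \code{observed_graph} (undirected
#'   skeleton), \code{pairs}, \code{depth} (named latent depths) and
#'   \code{params}.
#' @export
generate_world <- function(n_nodes = 300L, n_edges = 1200L, n_pairs = 40L,
                           cause_size = 5L, effect_size = 30L,
                           walk_length = 3L, noise = 0.1,
                           depth_bandwidth = 0.16, n_modules = 8L,
                           seed = 7L) {
  stopifnot(n_edges >= n_nodes, noise >= 0, noise <= 1, walk_length >= 1,
            depth_bandwidth > 0, n_modules >= 1L,
            n_edges <= n_nodes * (n_nodes - 1) / 2)
  if (cause_size > n_nodes || effect_size > n_nodes)
    stop("requested set sizes exceed the number of nodes")
  set.seed(seed)
  nodes <- sprintf("g%04d", seq_len(n_nodes))
  module <- rep(seq_len(n_modules), length.out = n_nodes)[sample.int(n_nodes)]
  depth <- stats::runif(n_nodes)

  # Hamiltonian cycle: modules in sequence, each in depth order ->
  # strong connectivity; within-module cycle edges run downhill
  ordn <- order(module, depth)
  from <- ordn
  to <- c(ordn[-1L], ordn[1L])
  nbrs <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    nbrs[[from[k]]] <- c(nbrs[[from[k]]], to[k])
    nbrs[[to[k]]] <- c(nbrs[[to[k]]], from[k])
  }
  deg <- tabulate(c(from, to), n_nodes)

  # within-module preferential attachment among depth-nearby nodes,
  # oriented downhill; existing neighbors are masked out, and a module
  # whose pairs are exhausted falls back to a cross-module partner (so
  # small worlds with many modules still terminate)
  extra <- n_edges - n_nodes
  ef <- integer(extra); et <- integer(extra)
  k <- 0L
  while (k < extra) {
    i <- sample.int(n_nodes, 1L, prob = deg + 1)
    kern <- (deg + 1) * exp(-abs(depth - depth[i]) / depth_bandwidth)
    kern[c(i, nbrs[[i]])] <- 0
    pj <- kern * (module == module[i])
    if (sum(pj) == 0) pj <- kern
    if (sum(pj) == 0) next      # node already adjacent to everyone
    j <- sample.int(n_nodes, 1L, prob = pj)
    k <- k + 1L
    if (depth[i] <= depth[j]) { ef[k] <- i; et[k] <- j } else { ef[k] <- j; et[k] <- i }
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
  }
  from <- c(from, ef); to <- c(to, et)
  w <- stats::runif(n_edges, 0.5, 1)
  true_graph <- ppi_graph(data.frame(u = nodes[from], v = nodes[to],
                                     weight = w, directed = TRUE,
                                     stringsAsFactors = FALSE))
  observed <- true_graph$edges
  observed$directed <- FALSE
  observed_graph <- ppi_graph(observed)

  # out-neighbor lists of the true directed graph
  ti <- match(true_graph$edges$u, nodes)
  tj <- match(true_graph$edges$v, nodes)
  out_nb <- split(tj, factor(ti, levels = seq_len(n_nodes)))

  walk_end <- function(start) {
    x <- start
    for (s in seq_len(walk_length)) {
      nb <- out_nb[[x]]
      if (!length(nb)) return(NA_integer_)  # dead end (cannot happen on the cycle-closed graph for s=1 but kept defensive)
      x <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
    }
    x
  }

  causes <- vector("list", n_pairs)
  effects <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    ci <- sample.int(n_nodes, cause_size)
    eff <- integer(0)
    attempts <- 0L
    while (length(eff) < effect_size && attempts < 60L * effect_size) {
      attempts <- attempts + 1L
      e <- walk_end(ci[sample.int(cause_size, 1L)])
      if (!is.na(e) && !(e %in% eff)) eff <- c(eff, e)
    }
    n_noise <- round(noise * length(eff))
    if (n_noise > 0L) {
      drop <- sample.int(length(eff), n_noise)
      pool <- setdiff(seq_len(n_nodes), eff[-drop])
      eff[drop] <- sample(pool, n_noise)
    }
    causes[[p]] <- nodes[ci]
    effects[[p]] <- nodes[eff]
  }
  pairs <- ce_pairs(causes, effects, ids = sprintf("cond%02d", seq_len(n_pairs)))

  names(depth) <- nodes
  names(module) <- nodes
  structure(list(true_graph = true_graph, observed_graph = observed_graph,
                 pairs = pairs, depth = depth, module = module,
                 params = list(n_nodes = n_nodes, n_edges = n_edges,
                               n_pairs = n_pairs, cause_size = cause_size,
                               effect_size = effect_size,
                               walk_length = walk_length, noise = noise,
                               depth_bandwidth = depth_bandwidth,
                               n_modules = n_modules, seed = seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic_world: %d nodes, %d directed edges, %d pairs (|C|=%d, |E|=%d, walk %d, noise %g, seed %d)\n",
              p$n_nodes, p$n_edges, p$n_pairs, p$cause_size, p$effect_size,
              p$walk_length, p$noise, p$seed))
  invisible(x)
}

#' Sample a directed benchmark from a synthetic world
#'
#' Draws \code{n_edges} true directed edges uniformly and passes them
#' through [preprocess_benchmark()] against the observed network, so the
#' result satisfies the conflict-removal and degree-balance invariants.
#'
#' @param world a [generate_world()] result.
#' @param n_edges number of true edges to sample.
#' @param seed seed for the sampling and balancing draws.
#' @return a \code{benchmark_set}.
#' @export
make_benchmark <- function(world, n_edges, seed = 1L) {
  ed <- world$true_graph$edges
  if (n_edges > nrow(ed))
    stop(sprintf("requested %d benchmark edges but the world has only %d", n_edges, nrow(ed)))
  set.seed(seed)
  pick <- sample.int(nrow(ed), n_edges)
  raw <- data.frame(u = ed$u[pick], v = ed$v[pick], source = "synthetic",
                    stringsAsFactors = FALSE)
  preprocess_benchmark(raw, world$observed_graph, seed = seed + 1L)
}
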