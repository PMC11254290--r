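# Shared fixture builders; everything is generated in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

triangle_graph <- function(w = c(1, 1, 1)) {
  ppi_graph(data.frame(u = c("a", "b", "a"), v = c("b", "c", "c"), weight = w))
}

path_graph <- function(nodes, weight = 1) {
  n <- length(nodes)
  ppi_graph(data.frame(u = nodes[-n], v = nodes[-1], weight = weight))
}

# directed chain n1 -> n2 -> ... -> nk
directed_chain <- function(nodes, weight = 1) {
  n <- length(nodes)
  ppi_graph(data.frame(u = nodes[-n], v = nodes[-1], weight = weight,
                       directed = TRUE))
}

# Erdos-Renyi undirected graph, resampled until connected
er_connected <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  repeat {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < p
    if (sum(keep) < n - 1) next
    ed <- data.frame(u = nodes[idx[keep, 1]], v = nodes[idx[keep, 2]],
                     weight = stats::runif(sum(keep), 0.5, 1.5))
    g <- ppi_graph(ed)
    if (length(g$nodes) == n &&
        igraph::is_connected(netorient:::as_igraph(g))) return(g)
  }
}

# a small world + assembled features, shared across model/d2d tests
tiny_feats <- function() {
  cached("tiny_feats", function() {
    w <- generate_world(n_nodes = 60, n_edges = 240, n_pairs = 6,
                        cause_size = 3, effect_size = 8, walk_length = 2,
                        noise = 0.1, seed = 3)
    bench <- make_benchmark(w, 120, seed = 5)
    feats <- assemble_features(w$observed_graph, w$pairs,
                               bench[, c("u", "v")])
    list(world = w, bench = bench, feats = feats)
  })
}
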