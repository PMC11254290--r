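#' Construct a (possibly partially directed) weighted interaction network
#'
#' The central network container. Edges are stored as a data frame with
#' columns \code{u}, \code{v}, \code{weight} and a logical \code{directed}
#' flag; undirected edges are canonicalized so that \code{u < v}
#' lexicographically, which makes duplicate detection and file round-trips
#' deterministic. Directed edges keep their \code{u -> v} order.
#'
#' @param edges data frame (or coercible) with columns \code{u}, \code{v},
#'   \code{weight} and optionally \code{directed} (logical or 0/1).
#' @param restrict if \code{TRUE}, restrict a disconnected network to its
#'   largest (strongly, when any edge is directed) connected component
#'   instead of keeping all nodes; the number of dropped nodes is reported
#'   via \code{message()}. Connectivity itself is only *required* by the
#'   normalization step, not by construction.
#' @return an object of class \code{ppi_graph} with elements \code{nodes}
#'   (sorted character vector) and \code{edges}.
#' @examples
#' g <- ppi_graph(data.frame(u = c("a", "b"), v = c("b", "c"), weight = 1))
#' g
#' @export
ppi_graph <- function(edges, restrict = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 3L) stop("edge table needs at least 3 columns (u, v, weight)")
  names(edges)[1:3] <- c("u", "v", "weight")
  if (ncol(edges) >= 4L) {
    names(edges)[4] <- "directed"
    edges$directed <- as.logical(as.integer(edges$directed))
  } else {
    edges$directed <- FALSE
  }
  edges <- edges[, c("u", "v", "weight", "directed")]
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  edges$weight <- as.numeric(edges$weight)

  if (anyNA(edges$weight)) stop("non-numeric edge weight")
  if (any(edges$weight <= 0)) {
    bad <- which(edges$weight <= 0)[1]
    stop(sprintf("nonpositive weight %g on edge (%s, %s)",
                 edges$weight[bad], edges$u[bad], edges$v[bad]))
  }
  if (any(edges$u == edges$v)) {
    bad <- which(edges$u == edges$v)[1]
    stop(sprintf("self-loop on node '%s' is not allowed", edges$u[bad]))
  }

  # canonical order for undirected edges; directed edges keep u -> v
  swap <- !edges$directed & edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp

  key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate edge between '%s' and '%s'",
                 sub("\r.*", "", d), sub(".*\r", "", d)))
  }

  nodes <- sort(unique(c(edges$u, edges$v)))
  ord <- order(edges$u, edges$v)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges), class = "ppi_graph")
  if (restrict) g <- largest_component(g)
  g
}

#' @export
print.ppi_graph <- function(x, ...) {
  nd <- sum(x$edges$directed)
  cat(sprintf("ppi_graph: %d nodes, %d edges (%d directed, %d undirected)\n",
              length(x$nodes), nrow(x$edges), nd, nrow(x$edges) - nd))
  invisible(x)
}

n_nodes <- function(g) length(g$nodes)
n_edges <- function(g) nrow(g$edges)

is_partially_directed <- function(g) any(g$edges$directed)

node_index <- function(g, ids) {
  i <- match(ids, g$nodes)
  if (anyNA(i)) stop(sprintf("unknown node id '%s'", ids[which(is.na(i))[1]]))
  i
}

#' Read a network from a tab-separated edge list
#'
#' Expected dialect: tab-separated columns \code{u}, \code{v}, \code{weight}
#' and, when \code{directed_column = TRUE}, a fourth 0/1 column marking
#' one-way edges. No header by default.
#'
#' @param path file path.
#' @param directed_column whether a fourth direction column is present.
#' @param header skip one header line.
#' @param restrict see [ppi_graph()].
#' @return a \code{ppi_graph}.
#' @export
read_edge_list <- function(path, directed_column = FALSE, header = FALSE,
                           restrict = FALSE) {
  lines <- readLines(path)
  if (header) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty edge list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (directed_column) 4L else 3L
  nf <- lengths(parts)
  if (any(nf < need)) {
    bad <- which(nf < need)[1]
    stop(sprintf("malformed line %d in %s: expected %d tab-separated fields, got %d",
                 bad + as.integer(header), path, need, nf[bad]))
  }
  u <- vapply(parts, `[[`, "", 1L)
  v <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop(sprintf("malformed line %d in %s: non-numeric weight",
                 bad + as.integer(header), path))
  }
  ed <- data.frame(u = u, v = v, weight = w, stringsAsFactors = FALSE)
  if (directed_column) ed$directed <- as.integer(vapply(parts, `[[`, "", 4L))
  ppi_graph(ed, restrict = restrict)
}

#' Write a network as a tab-separated edge list
#'
#' Emits the same dialect [read_edge_list()] consumes; the direction column
#' is written only when the graph contains directed edges or
#' \code{directed_column = TRUE}.
#'
#' @param g a \code{ppi_graph}.
#' @param path output file.
#' @param directed_column force the 4-column dialect.
#' @param header write a header line.
#' @export
write_edge_list <- function(g, path, directed_column = is_partially_directed(g),
                            header = FALSE) {
  ed <- g$edges
  cols <- if (directed_column) {
    cbind(ed$u, ed$v, format(ed$weight, trim = TRUE, scientific = FALSE, digits = 15),
          as.integer(ed$directed))
  } else {
    cbind(ed$u, ed$v, format(ed$weight, trim = TRUE, scientific = FALSE, digits = 15))
  }
  lines <- apply(cols, 1L, paste, collapse = "\t")
  if (header) {
    hd <- if (directed_column) "u\tv\tweight\tdirected" else "u\tv\tweight"
    lines <- c(hd, lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Arc-level sparse adjacency matrix
#'
#' \code{A[i, j]} holds the weight of arc \code{i -> j}; undirected edges
#' contribute both arcs. Row/column order follows \code{g$nodes}.
#'
#' @param g a \code{ppi_graph}.
#' @param skeleton ignore directions and return the symmetric adjacency of
#'   the undirected skeleton.
#' @return a sparse \code{dgCMatrix}.
#' @export
adjacency <- function(g, skeleton = FALSE) {
  n <- n_nodes(g)
  ed <- g$edges
  i <- match(ed$u, g$nodes)
  j <- match(ed$v, g$nodes)
  if (skeleton) {
    ii <- c(i, j); jj <- c(j, i); ww <- c(ed$weight, ed$weight)
  } else {
    back <- !ed$directed
    ii <- c(i, j[back]); jj <- c(j, i[back]); ww <- c(ed$weight, ed$weight[back])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n),
                       dimnames = list(g$nodes, g$nodes))
}

#' Weighted node degrees of the undirected skeleton
#' @param g a \code{ppi_graph}.
#' @return named numeric vector of weighted degrees.
#' @export
weighted_degrees <- function(g) {
  d <- numeric(n_nodes(g))
  i <- match(g$edges$u, g$nodes); j <- match(g$edges$v, g$nodes)
  for (k in seq_along(i)) {
    d[i[k]] <- d[i[k]] + g$edges$weight[k]
    d[j[k]] <- d[j[k]] + g$edges$weight[k]
  }
  names(d) <- g$nodes
  d
}

as_igraph <- function(g, skeleton = FALSE) {
  ed <- g$edges
  if (skeleton || !is_partially_directed(g)) {
    igraph::graph_from_data_frame(ed[, c("u", "v")], directed = FALSE,
                                  vertices = g$nodes)
  } else {
    back <- !ed$directed
    arcs <- rbind(ed[, c("u", "v")],
                  data.frame(u = ed$v[back], v = ed$u[back]))
    igraph::graph_from_data_frame(arcs, directed = TRUE, vertices = g$nodes)
  }
}

check_connected <- function(g, mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  ig <- as_igraph(g, skeleton = (mode == "weak"))
  comp <- igraph::components(ig, mode = if (mode == "strong") "strong" else "weak")
  if (comp$no > 1L) {
    sizes <- sort(comp$csize, decreasing = TRUE)
    if (mode == "strong")
      stop(sprintf("network is not strongly connected: largest strongly connected component has %d of %d nodes",
                   sizes[1], length(g$nodes)))
    stop(sprintf("network is disconnected: %d components of sizes %s",
                 comp$no, paste(sizes, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Restrict a network to its largest (strongly) connected component
#'
#' Uses weak components for fully undirected graphs and strong components
#' when any edge is directed. The number of dropped nodes is messaged.
#'
#' @param g a \code{ppi_graph}.
#' @return a \code{ppi_graph} on the surviving nodes.
#' @export
largest_component <- function(g) {
  mode <- if (is_partially_directed(g)) "strong" else "weak"
  ig <- as_igraph(g, skeleton = (mode == "weak"))
  comp <- igraph::components(ig, mode = mode)
  keep_id <- which.max(comp$csize)
  keep <- g$nodes[comp$membership == keep_id]
  dropped <- length(g$nodes) - length(keep)
  if (dropped > 0L)
    message(sprintf("largest_component: dropped %d of %d nodes", dropped, length(g$nodes)))
  ed <- g$edges[g$edges$u %in% keep & g$edges$v %in% keep, , drop = FALSE]
  ppi_graph(ed)
}

#' Symmetric walk-matrix normalization
#'
#' Builds \eqn{W = D^{-1/2} A D^{-1/2}} from the (undirected, connected)
#' network, where \eqn{D} is the diagonal matrix of weighted degrees. The
#' result is symmetric with spectral radius at most 1, so the propagation
#' fixed point exists for any restart parameter \eqn{\alpha < 1}.
#'
#' @param g an undirected, connected \code{ppi_graph}.
#' @return sparse symmetric walk matrix.
#' @export
normalize_symmetric <- function(g) {
  if (is_partially_directed(g))
    stop("symmetric normalization requires a fully undirected network")
  check_connected(g, "weak")
  A <- adjacency(g)
  dinv <- 1 / sqrt(Matrix::rowSums(A))
  Dinv <- Matrix::Diagonal(x = dinv)
  W <- Dinv %*% A %*% Dinv
  dimnames(W) <- list(g$nodes, g$nodes)
  W
}

#' Column-stochastic walk-matrix normalization
#'
#' Builds the directed walk matrix \eqn{W = A D^{-1}} used when the network
#' carries (some) directions, with \code{W[v, u]} the normalized weight of
#' arc \code{u -> v}. With \code{degree = "out"} (default) \eqn{D} holds
#' out-degrees, every column sums to exactly 1, and strong connectivity is
#' required. With \code{degree = "skeleton"} \eqn{D} holds total weighted
#' degrees of the undirected skeleton: flipping an edge then changes
#' reachability but not normalization mass, columns sum to at most 1, and
#' the propagation iteration converges on any partially oriented graph, so
#' no connectivity check is imposed.
#'
#' @param g a \code{ppi_graph} (directions honored).
#' @param degree degree convention, \code{"out"} or \code{"skeleton"}.
#' @return sparse walk matrix with \code{W[v, u]} = weight of arc
#'   \code{u -> v} over \code{degree(u)}.
#' @export
normalize_column <- function(g, degree = c("out", "skeleton")) {
  degree <- match.arg(degree)
  A <- adjacency(g)              # A[i, j] = arc i -> j
  if (degree == "out") {
    check_connected(g, "strong")
    d <- Matrix::rowSums(A)
  } else {
    d <- Matrix::rowSums(adjacency(g, skeleton = TRUE))
  }
  # W = t(A) D^{-1}: column u scaled by 1/d(u)
  W <- Matrix::t(A) %*% Matrix::Diagonal(x = 1 / d)
  dimnames(W) <- list(g$nodes, g$nodes)
  W
}

#' Commit undirected edges to a single direction
#'
#' Each pair \code{(u, v)} in \code{directed_edges} must be an existing
#' undirected edge; it becomes one-way \code{u -> v}, keeping its weight.
#' Edges not listed remain two-way.
#'
#' @param g a \code{ppi_graph}.
#' @param directed_edges two-column matrix or data frame of (from, to) pairs.
#' @return a partially directed \code{ppi_graph}.
#' @export
orient_edges <- function(g, directed_edges) {
  de <- as.data.frame(directed_edges, stringsAsFactors = FALSE)
  if (nrow(de) == 0L) return(g)
  from <- as.character(de[[1]]); to <- as.character(de[[2]])
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("conflicting orientation request for edge (%s, %s)", from[d], to[d]))
  }
  ed <- g$edges
  ekey <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "\r")
  hit <- match(key, ekey)
  if (anyNA(hit)) {
    m <- which(is.na(hit))[1]
    stop(sprintf("edge (%s, %s) is not in the network", from[m], to[m]))
  }
  if (any(ed$directed[hit]))
    stop("cannot re-orient an already directed edge")
  ed$u[hit] <- from; ed$v[hit] <- to
  ed$directed[hit] <- TRUE
  ppi_graph(ed)
}

#' Reverse every one-way edge
#'
#' Used by gene prioritization: after orienting a network cause-to-effect,
#' reversing all arcs lets propagation from effect genes flow toward their
#' upstream causes. Two-way edges are unchanged; applying the operation
#' twice restores the original network.
#'
#' @param g a \code{ppi_graph}.
#' @return a \code{ppi_graph} with all directed edges reversed.
#' @export
flip_directions <- function(g) {
  ed <- g$edges
  d <- ed$directed
  tmp <- ed$u[d]; ed$u[d] <- ed$v[d]; ed$v[d] <- tmp
  ppi_graph(ed)
}
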