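#' Undirected simple graph over 0-based integer node ids
#'
#' The central container of the package: a fixed node count together with a
#' canonical edge set. Edges are stored as a two-column integer matrix with
#' `u < v` in every row, rows ordered lexicographically, so that two graphs
#' with the same edge set compare identical. Isolated nodes are allowed:
#' the node count is independent of the edge set.
#'
#' @param n_nodes Positive integer, number of nodes. Node ids are
#'   `0 .. n_nodes - 1`.
#' @param edges Two-column matrix (or empty) of 0-based node ids; one row
#'   per undirected edge. Orientation and row order are irrelevant.
#' @return An object of class `net_graph` with fields `n_nodes` and `edges`.
#' @examples
#' g <- net_graph(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
#' n_edges(g)
#' degrees(g)
#' @export
net_graph <- function(n_nodes, edges = matrix(integer(0), ncol = 2)) {
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L)
    stop("n_nodes must be a single positive integer")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  }
  if (ncol(edges) != 2L)
    stop("edges must be a two-column matrix")
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L) {
    if (anyNA(edges)) stop("edges must not contain NA")
    if (min(edges) < 0L || max(edges) >= n_nodes)
      stop("edge endpoints must lie in [0, n_nodes)")
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed")
    u <- pmin(edges[, 1], edges[, 2])
    v <- pmax(edges[, 1], edges[, 2])
    o <- order(u, v)
    u <- u[o]; v <- v[o]
    if (anyDuplicated(u * n_nodes + v))
      stop("duplicate edges are not allowed")
    edges <- cbind(u, v, deparse.level = 0)
  }
  dimnames(edges) <- NULL
  structure(list(n_nodes = n_nodes, edges = edges), class = "net_graph")
}

#' @export
print.net_graph <- function(x, ...) {
  cat(sprintf("net_graph: %d nodes, %d edges, mean degree %.2f\n",
              x$n_nodes, nrow(x$edges), 2 * nrow(x$edges) / x$n_nodes))
  invisible(x)
}

#' @rdname net_graph
#' @param g A `net_graph`.
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "net_graph"))
  nrow(g$edges)
}

#' Node degrees
#'
#' @param g A `net_graph`.
#' @return Integer vector of length `n_nodes` with the degree of each node
#'   (position `i` is node id `i - 1`).
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "net_graph"))
  tabulate(c(g$edges[, 1], g$edges[, 2]) + 1L, nbins = g$n_nodes)
}

#' Convert to / from igraph
#'
#' @param g A `net_graph`.
#' @return `as_igraph()`: an undirected [igraph::igraph] graph with
#'   `n_nodes` vertices (vertex `i` is node id `i - 1`).
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "net_graph"))
  ig <- igraph::make_empty_graph(g$n_nodes, directed = FALSE)
  if (nrow(g$edges) > 0L)
    ig <- igraph::add_edges(ig, as.vector(t(g$edges + 1L)))
  ig
}

#' @rdname as_igraph
#' @param ig An undirected simple igraph graph.
#' @export
from_igraph <- function(ig) {
  el <- igraph::as_edgelist(ig, names = FALSE)
  net_graph(igraph::vcount(ig), el - 1L)
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Grows a scale-free contact network from `m` initially isolated seed
#' nodes; each of the remaining `n - m` nodes attaches with `m` edges to
#' existing nodes chosen with probability proportional to their current
#' degree (plus a unit appeal so zero-degree seed nodes can be chosen).
#' The edge count is therefore exactly `(n - m) * m`: with `n = 100`,
#' `m = 10` this gives 900 edges and mean degree 18, the scale used
#' throughout the package's examples.
#'
#' @param n Number of nodes.
#' @param m Edges added per new node; `1 <= m < n`.
#' @param seed Integer RNG seed.
#' @return A `net_graph`.
#' @examples
#' g <- generate_ba(100, 10, seed = 1)
#' n_edges(g) # 900
#' @export
generate_ba <- function(n, m, seed) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1L || m >= n) stop("require 1 <= m < n")
  set.seed(seed)
  ig <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE,
                          start.graph = igraph::make_empty_graph(m, directed = FALSE))
  from_igraph(ig)
}

#' Connection radius of a random geometric graph for a target mean degree
#'
#' For `n` points uniform in the unit square with hard (non-periodic)
#' boundaries, the expected area of the radius-`r` disc clipped to the
#' square is `pi r^2 - 8 r^3 / 3 + r^4 / 2` (valid for `r <= 1`), so the
#' expected degree is `(n - 1)` times that. This solves for the radius
#' giving a requested mean degree; boundary clipping makes the radius
#' noticeably larger than the toroidal value `sqrt(k / (pi (n - 1)))`.
#'
#' @param n Number of nodes.
#' @param target_degree Desired expected degree.
#' @return The connection radius.
#' @examples
#' rg_radius_for_degree(100, 18) # ~0.272
#' @export
rg_radius_for_degree <- function(n, target_degree) {
  stopifnot(n >= 2, target_degree > 0, target_degree <= n - 1)
  area <- function(r) pi * r^2 - 8 * r^3 / 3 + r^4 / 2
  f <- function(r) (n - 1) * area(r) - target_degree
  stats::uniroot(f, c(1e-6, 1), tol = 1e-10)$root
}

#' Random geometric graph in the unit square
#'
#' Scatters `n` points uniformly in the unit square (hard boundary, no
#' wrap-around) and connects every pair at Euclidean distance at most
#' `radius`. The default radius targets mean degree 18, matching the
#' package's standard 100-node, ~900-edge setting; boundary clipping is
#' accounted for by [rg_radius_for_degree()]. Edge counts fluctuate from
#' seed to seed because positions are random.
#'
#' @param n Number of nodes.
#' @param radius Connection radius; values above `sqrt(2)` are capped (the
#'   graph is then complete).
#' @param seed Integer RNG seed.
#' @return A `net_graph` with attribute `"coords"` holding the point
#'   coordinates (n x 2 matrix).
#' @examples
#' g <- generate_rg(100, seed = 1)
#' mean(degrees(g)) # ~18
#' @export
generate_rg <- function(n, radius = rg_radius_for_degree(n, 18), seed) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be positive")
  if (radius <= 0) stop("radius must be positive")
  radius <- min(radius, sqrt(2))
  set.seed(seed)
  xy <- cbind(runif(n), runif(n))
  if (n >= 2L) {
    d <- as.matrix(stats::dist(xy))
    w <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
    g <- net_graph(n, w - 1L)
  } else {
    g <- net_graph(n)
  }
  attr(g, "coords") <- xy
  g
}

#' Degree histogram
#'
#' @param g A `net_graph`.
#' @return A data frame of class `degree_histogram` with columns `degree`
#'   and `count`; counts sum to `n_nodes`.
#' @examples
#' degree_histogram(generate_ba(50, 3, seed = 1))
#' @export
degree_histogram <- function(g) {
  d <- degrees(g)
  tb <- table(factor(d, levels = 0:max(d)))
  out <- data.frame(degree = as.integer(names(tb)), count = as.integer(tb))
  out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("degree_histogram", "data.frame")
  out
}

#' Connected-component summary
#'
#' Component count and component sizes (sorted descending), computed by
#' standard graph traversal via igraph. The first size is the giant
#' component.
#'
#' @param g A `net_graph`.
#' @return List of class `component_summary` with `n_components`,
#'   `component_sizes` (descending) and `giant_size`.
#' @examples
#' component_summary(net_graph(5, rbind(c(0, 1), c(1, 2))))
#' @export
component_summary <- function(g) {
  comp <- igraph::components(as_igraph(g))
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  structure(list(n_components = as.integer(comp$no),
                 component_sizes = sizes,
                 giant_size = sizes[1]),
            class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf("%d component(s); sizes: %s\n", x$n_components,
              paste(head(x$component_sizes, 10), collapse = " ")))
  invisible(x)
}

#' @export
as.data.frame.component_summary <- function(x, ...) {
  data.frame(component_rank = seq_along(x$component_sizes),
             size = x$component_sizes)
}

#' Read / write two-column edge-list files
#'
#' Plain-text whitespace-separated edge lists with 0-based integer node
#' ids, one edge per line. Lines starting with `#` are comments; a header
#' comment `# n_nodes=<int>` fixes the node count (needed to represent
#' trailing isolated nodes), otherwise the node count is the largest id
#' plus one. Self-loops and duplicate edges are rejected with the
#' offending line number. `write_edge_list()` always emits the header, so
#' write-then-read is the identity on canonical graphs.
#'
#' @param path File path.
#' @return `read_edge_list()`: a `net_graph`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  n_nodes <- NA_integer_
  hdr <- grep("^#\\s*n_nodes\\s*=", lines)
  if (length(hdr) > 0L)
    n_nodes <- as.integer(sub("^#\\s*n_nodes\\s*=\\s*(\\d+).*$", "\\1",
                              lines[hdr[1]]))
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(rows, length, 1L) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("line %d: expected two whitespace-separated integers",
                 lineno[bad[1]]))
  u <- suppressWarnings(as.integer(vapply(rows, `[`, "", 1L)))
  v <- suppressWarnings(as.integer(vapply(rows, `[`, "", 2L)))
  if (anyNA(u) || anyNA(v))
    stop(sprintf("line %d: not an integer",
                 lineno[which(is.na(u) | is.na(v))[1]]))
  loop <- which(u == v)
  if (length(loop) > 0L)
    stop(sprintf("line %d: self-loop '%d %d'", lineno[loop[1]],
                 u[loop[1]], v[loop[1]]))
  if (is.na(n_nodes))
    n_nodes <- if (length(u) > 0L) max(u, v) + 1L else 1L
  key <- pmin(u, v) * as.double(n_nodes) + pmax(u, v)
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    stop(sprintf("line %d: duplicate edge '%d %d'", lineno[dup[1]],
                 u[dup[1]], v[dup[1]]))
  net_graph(n_nodes, cbind(u, v))
}

#' @rdname read_edge_list
#' @param g A `net_graph`.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "net_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d", g$n_nodes), con)
  if (nrow(g$edges) > 0L)
    writeLines(paste(g$edges[, 1], g$edges[, 2], sep = "\t"), con)
  invisible(path)
}
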