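# Link-removal (social distancing) strategies. All strategies return a
# subgraph on the unchanged node set; for the rate-parameterized ones the
# number of removed edges is round-half-up(rho * E), computed once from the
# original edge count so that strategies are comparable at equal rho.

round_half_up <- function(x) floor(x + 0.5)

.check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho <= 0 || rho >= 1)
    stop("rho must be a single number in (0, 1)")
}

#' Number of edges removed at contact-reduction rate rho
#'
#' `round(rho * E)` with half-up rounding, applied once to the original
#' edge count; all rate-parameterized strategies remove exactly this many
#' edges.
#'
#' @param g A `net_graph`.
#' @param rho Contact-reduction rate in (0, 1).
#' @export
n_removed_edges <- function(g, rho) {
  .check_rho(rho)
  as.integer(round_half_up(rho * n_edges(g)))
}

.subgraph_keep <- function(g, keep_idx) {
  net_graph(g$n_nodes, g$edges[keep_idx, , drop = FALSE])
}

# uniform retained subset without re-seeding (callers manage the RNG)
.random_keep_idx <- function(E, n_keep) {
  sort(sample.int(E, n_keep))
}

#' Uniformly random link removal (the generic ensemble)
#'
#' Retains a uniformly random subset of `E - round(rho * E)` edges: a draw
#' from the generic ensemble of rate-`rho` contact reductions, the
#' baseline against which targeted strategies are compared.
#'
#' @param g A `net_graph`.
#' @param rho Contact-reduction rate in (0, 1).
#' @param seed Integer RNG seed.
#' @return A `net_graph` subgraph of `g`.
#' @examples
#' n_edges(random_removal(generate_ba(100, 10, seed = 1), 0.4, seed = 2)) # 540
#' @export
random_removal <- function(g, rho, seed) {
  stopifnot(inherits(g, "net_graph"))
  n_rm <- n_removed_edges(g, rho)
  set.seed(seed)
  .subgraph_keep(g, .random_keep_idx(n_edges(g), n_edges(g) - n_rm))
}

#' Degree-product link removal
#'
#' Iteratively deletes one edge maximizing the product of its endpoints'
#' current degrees (ties broken uniformly at random), recomputing degrees
#' after every deletion, until `round(rho * E)` edges are gone. A local,
#' degree-homogenizing heuristic: hubs lose links first, so the surviving
#' degree distribution is much more sharply peaked than under random
#' removal.
#'
#' @inheritParams random_removal
#' @return A `net_graph` subgraph of `g`.
#' @export
degree_product_removal <- function(g, rho, seed) {
  stopifnot(inherits(g, "net_graph"))
  n_rm <- n_removed_edges(g, rho)
  set.seed(seed)
  alive <- rep(TRUE, n_edges(g))
  deg <- degrees(g)
  u <- g$edges[, 1] + 1L
  v <- g$edges[, 2] + 1L
  for (i in seq_len(n_rm)) {
    idx <- which(alive)
    p <- deg[u[idx]] * deg[v[idx]]
    cand <- idx[p == max(p)]
    e <- cand[sample.int(length(cand), 1L)]
    alive[e] <- FALSE
    deg[u[e]] <- deg[u[e]] - 1L
    deg[v[e]] <- deg[v[e]] - 1L
  }
  .subgraph_keep(g, which(alive))
}

#' Degree-cap link removal
#'
#' Processes nodes in the given order; every node whose current degree
#' exceeds `k_max` has a uniformly random selection of all but `k_max` of
#' its surviving links removed. After the pass no node's degree exceeds
#' `k_max`. With ascending node ids on preferential-attachment graphs the
#' early (high-degree) nodes are capped first; `order = "random"` shuffles
#' the ids, which is the effective behavior on geometric graphs anyway.
#'
#' @param g A `net_graph`.
#' @param k_max Non-negative degree cap.
#' @param seed Integer RNG seed.
#' @param order `"ascending"` (node id order), `"random"`, or an explicit
#'   permutation of the 0-based node ids.
#' @return A `net_graph` with maximum degree at most `k_max`.
#' @export
degree_cap_removal <- function(g, k_max, seed, order = "ascending") {
  stopifnot(inherits(g, "net_graph"), k_max >= 0)
  set.seed(seed)
  ord <- if (is.character(order)) {
    switch(match.arg(order, c("ascending", "random")),
           ascending = seq_len(g$n_nodes),
           random = sample.int(g$n_nodes))
  } else {
    stopifnot(length(order) == g$n_nodes,
              setequal(order, 0:(g$n_nodes - 1L)))
    as.integer(order) + 1L
  }
  alive <- rep(TRUE, n_edges(g))
  # incident edge indices per node (1-based node position)
  inc <- split(rep(seq_len(n_edges(g)), 2L),
               factor(c(g$edges[, 1], g$edges[, 2]) + 1L,
                      levels = seq_len(g$n_nodes)))
  for (node in ord) {
    mine <- inc[[node]][alive[inc[[node]]]]
    excess <- length(mine) - k_max
    if (excess > 0L)
      alive[mine[sample.int(length(mine), excess)]] <- FALSE
  }
  .subgraph_keep(g, which(alive))
}

#' Degree-cap removal matched to a target removal rate
#'
#' The degree-cap rule removes a cap-dependent number of edges; to compare
#' it with the rate-parameterized strategies this finds the tightest
#' (smallest) `k_max` whose cap pass removes at most `round(rho * E)`
#' edges, applies it, and then removes additional uniformly random
#' surviving edges to hit the target count exactly. In the `rho -> 0`
#' limit the selected cap is the maximum degree and the result is a pure
#' random top-up.
#'
#' @inheritParams random_removal
#' @param order Passed to [degree_cap_removal()].
#' @return A `net_graph` with exactly `E - round(rho * E)` edges; the
#'   selected cap is attached as attribute `"k_max"`.
#' @export
degree_cap_for_rate <- function(g, rho, seed, order = "ascending") {
  stopifnot(inherits(g, "net_graph"))
  target <- n_removed_edges(g, rho)
  kmax_hi <- max(degrees(g))
  chosen <- NULL
  chosen_k <- kmax_hi
  for (k in seq(kmax_hi, 0L)) {
    cand <- degree_cap_removal(g, k, seed, order)
    if (n_edges(g) - n_edges(cand) > target) break
    chosen <- cand
    chosen_k <- k
  }
  if (is.null(chosen)) { # even the loosest cap over-removes (cannot happen for k = max degree)
    chosen <- g
    chosen_k <- kmax_hi
  }
  remaining <- target - (n_edges(g) - n_edges(chosen))
  if (remaining > 0L) {
    set.seed(seed + 1L)
    keep <- .random_keep_idx(n_edges(chosen), n_edges(chosen) - remaining)
    chosen <- .subgraph_keep(chosen, keep)
  }
  attr(chosen, "k_max") <- chosen_k
  chosen
}

#' Edge-betweenness link removal
#'
#' Iteratively deletes the edge with the highest shortest-path edge
#' betweenness (recomputed after every deletion, ties broken uniformly at
#' random) until `round(rho * E)` edges are removed. Included as a
#' global-information baseline; concentrating removals on bridges tends to
#' fragment the network without flattening its dense cores, so it reduces
#' the spectral radius less than uniform removal.
#'
#' @inheritParams random_removal
#' @return A `net_graph` subgraph of `g`.
#' @export
edge_betweenness_removal <- function(g, rho, seed = 1L) {
  stopifnot(inherits(g, "net_graph"))
  n_rm <- n_removed_edges(g, rho)
  set.seed(seed)
  ig <- as_igraph(g)
  for (i in seq_len(n_rm)) {
    eb <- igraph::edge_betweenness(ig, directed = FALSE)
    cand <- which(eb == max(eb))
    ig <- igraph::delete_edges(ig, cand[sample.int(length(cand), 1L)])
  }
  from_igraph(ig)
}
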