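# Small graph builders and independent oracles used across the tests.

path_graph <- function(n) {
  net_graph(n, cbind(0:(n - 2L), 1:(n - 1L)))
}

complete_graph <- function(n) {
  net_graph(n, t(combn(0:(n - 1L), 2L)))
}

star_graph <- function(leaves) {
  net_graph(leaves + 1L, cbind(0L, seq_len(leaves)))
}

# disjoint union, relabeling the second graph's ids upward
disjoint_union <- function(g1, g2) {
  net_graph(g1$n_nodes + g2$n_nodes,
            rbind(g1$edges, g2$edges + g1$n_nodes))
}

random_gnp <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(0:(n - 1L), 2L))
  net_graph(n, pairs[runif(nrow(pairs)) < p, , drop = FALSE])
}

# dense-eigendecomposition spectral radius, independent of the package's
# power-iteration backend
dense_lambda <- function(g) {
  if (nrow(g$edges) == 0L) return(0)
  A <- matrix(0, g$n_nodes, g$n_nodes)
  A[g$edges + 1L] <- 1
  A[g$edges[, c(2, 1), drop = FALSE] + 1L] <- 1
  max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
}

# Exact final-size distribution of the synchronous SIR process with
# certain recovery (delta = 1), by exhaustive enumeration over the
# per-step infection outcomes. Returns a named probability vector over
# final cumulative-infected counts.
sir_final_size_exact <- function(g, beta, seed_nodes) {
  n <- g$n_nodes
  nbrs <- lapply(seq_len(n) - 1L, function(u) {
    e <- g$edges
    c(e[e[, 1] == u, 2], e[e[, 2] == u, 1])
  })
  out <- new.env()
  assign_prob <- function(size, p) {
    key <- as.character(size)
    cur <- if (exists(key, envir = out, inherits = FALSE)) out[[key]] else 0
    out[[key]] <- cur + p
  }
  recurse <- function(infected, recovered, p) {
    if (length(infected) == 0L) {
      assign_prob(length(recovered), p)
      return(invisible())
    }
    sus <- setdiff(0:(n - 1L), c(infected, recovered))
    p_inf <- vapply(sus, function(u) {
      k <- sum(nbrs[[u + 1L]] %in% infected)
      1 - (1 - beta)^k
    }, numeric(1))
    at_risk <- sus[p_inf > 0]
    p_at <- p_inf[p_inf > 0]
    m <- length(at_risk)
    for (mask in 0:(2^m - 1)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
      pr <- prod(ifelse(sel, p_at, 1 - p_at))
      if (pr > 0)
        recurse(at_risk[sel], c(recovered, infected), p * pr)
    }
  }
  recurse(sort(seed_nodes), integer(0), 1)
  v <- unlist(as.list(out))
  v[order(as.integer(names(v)))]
}
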