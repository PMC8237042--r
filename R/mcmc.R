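# Metropolis-Hastings sampler of the canonical network ensemble
#   p(N) = exp(-nu * lambda_max(N)) / Z
# over subgraphs of a social graph with a fixed number of removed edges.
# The proposal swaps one uniformly chosen kept edge with one uniformly
# chosen removed edge; that proposal is symmetric, so the Metropolis ratio
# is exactly min(1, exp(nu * (e_cur - e_prop))) with no Hastings
# correction. At nu = 0 every proposal is accepted and the chain samples
# the generic (uniform) ensemble; at large nu it concentrates on
# subgraphs with small spectral radius (the well-controlling ensemble).

#' Metropolis acceptance probability
#'
#' `min(1, exp(nu * (e_current - e_proposed)))`: proposals that do not
#' increase the energy (the spectral radius of the kept subgraph) are
#' always accepted; increases are accepted with exponentially small
#' probability scaled by the inverse genericity `nu`.
#'
#' @param e_current,e_proposed Current and proposed energies.
#' @param nu Inverse genericity, `nu >= 0`.
#' @return Probability in \[0, 1\] (vectorized).
#' @examples
#' acceptance_probability(3, 3.5, nu = 2) # exp(-1)
#' @export
acceptance_probability <- function(e_current, e_proposed, nu) {
  if (any(nu < 0)) stop("nu must be non-negative")
  pmin(1, exp(nu * (e_current - e_proposed)))
}

#' MCMC state: a partition of the edge set into kept and removed edges
#'
#' @param g The original `net_graph`.
#' @param rho Removal rate in (0, 1); `round(rho * E)` edges are removed.
#' @param seed Integer RNG seed for the initial uniform draw from the
#'   generic ensemble.
#' @return List of class `mcmc_state`: the original graph, integer index
#'   vectors `kept` and `removed` into its edge rows, the current
#'   `energy` (spectral radius of the kept subgraph) and the `step`
#'   counter.
#' @export
mcmc_state <- function(g, rho, seed) {
  stopifnot(inherits(g, "net_graph"))
  n_rm <- n_removed_edges(g, rho)
  E <- n_edges(g)
  if (n_rm == 0L || n_rm == E)
    stop("degenerate rho: removal must leave both kept and removed edges non-empty")
  set.seed(seed)
  kept <- .random_keep_idx(E, E - n_rm)
  st <- structure(list(graph = g, kept = kept,
                       removed = setdiff(seq_len(E), kept),
                       energy = NA_real_, step = 0L),
                  class = "mcmc_state")
  st$energy <- largest_eigenvalue(state_graph(st))
  st
}

#' @rdname mcmc_state
#' @param state An `mcmc_state`.
#' @return `state_graph()`: the kept subgraph as a `net_graph`.
#' @export
state_graph <- function(state) {
  stopifnot(inherits(state, "mcmc_state"))
  .subgraph_keep(state$graph, state$kept)
}

#' Propose an edge swap
#'
#' Draws one kept edge and one removed edge uniformly at random and
#' exchanges their memberships; all other edges are untouched, so the
#' proposal differs from the state in exactly two edge memberships and the
#' removed-edge count is conserved. Uses the current RNG stream.
#'
#' @param state An `mcmc_state` with non-empty kept and removed sets.
#' @return The proposed `mcmc_state` (energy recomputed, step incremented).
#' @export
propose_swap <- function(state) {
  stopifnot(inherits(state, "mcmc_state"))
  if (length(state$kept) == 0L || length(state$removed) == 0L)
    stop("cannot propose a swap: kept or removed edge set is empty")
  i <- sample.int(length(state$kept), 1L)
  j <- sample.int(length(state$removed), 1L)
  tmp <- state$kept[i]
  state$kept[i] <- state$removed[j]
  state$removed[j] <- tmp
  state$step <- state$step + 1L
  state$energy <- largest_eigenvalue(state_graph(state))
  state
}

#' Run the Metropolis edge-swap sampler
#'
#' Starts from a uniform draw of the generic ensemble (identical to
#' [random_removal()] with the same seed), then performs `steps`
#' Metropolis updates: propose an edge swap, accept with
#' [acceptance_probability()], record the energy. The spectral radius is
#' recomputed for every proposal by warm-started Lanczos iteration at
#' absolute tolerance `tol`. Around 11,000 steps bring 100-node, ~900-edge
#' networks to a steady state of `lambda_max`.
#'
#' @param g A `net_graph`.
#' @param rho Removal rate in (0, 1).
#' @param nu Inverse genericity, `nu >= 0`.
#' @param steps Number of Metropolis steps (`>= 0`).
#' @param seed Integer RNG seed.
#' @param tol Eigenvalue tolerance.
#' @param record_states If `TRUE`, also record the removed-edge index set
#'   at every step (matrix `steps x n_removed`; intended for small
#'   instances, e.g. occupancy checks against exact enumeration).
#' @return List of class `mcmc_trace`: per-step `energies` (energy after
#'   each step) and `accepted` flags, `initial_energy`, `final_energy`,
#'   the `final_graph`, optionally `removed_history`, and the `config`.
#' @examples
#' tr <- mcmc_run(generate_ba(30, 3, seed = 1), rho = 0.4, nu = 100,
#'                steps = 200, seed = 2)
#' tr$final_energy <= tr$initial_energy
#' @export
mcmc_run <- function(g, rho, nu, steps, seed, tol = 1e-8,
                     record_states = FALSE) {
  stopifnot(inherits(g, "net_graph"), nu >= 0, steps >= 0)
  n_rm <- n_removed_edges(g, rho)
  E <- n_edges(g)
  if (n_rm == 0L || n_rm == E)
    stop("degenerate rho: removal must leave both kept and removed edges non-empty")
  set.seed(seed)
  kept0 <- .random_keep_idx(E, E - n_rm)
  if (steps == 0L) {
    g0 <- .subgraph_keep(g, kept0)
    e0 <- largest_eigenvalue(g0, tol = tol)
    res <- list(energies = numeric(0), accepted = logical(0),
                initial_energy = e0, final_energy = e0, final_graph = g0,
                removed_history = NULL,
                config = list(rho = rho, nu = nu, steps = 0L, seed = seed,
                              tol = tol))
    class(res) <- "mcmc_trace"
    return(res)
  }
  eng <- mcmc_engine(g$n_nodes, g$edges[, 1], g$edges[, 2], kept0 - 1L,
                     nu, as.integer(steps), tol, 100000L,
                     isTRUE(record_states))
  res <- list(energies = eng$energies, accepted = as.logical(eng$accepted),
              initial_energy = eng$initial_energy,
              final_energy = eng$final_energy,
              final_graph = .subgraph_keep(g, sort(eng$kept_final + 1L)),
              removed_history = if (record_states) eng$removed_history + 1L else NULL,
              config = list(rho = rho, nu = nu, steps = as.integer(steps),
                            seed = seed, tol = tol))
  class(res) <- "mcmc_trace"
  res
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf(
    "mcmc_trace: %d steps (rho=%.2f, nu=%g), lambda_max %.3f -> %.3f, acceptance %.1f%%\n",
    x$config$steps, x$config$rho, x$config$nu, x$initial_energy,
    x$final_energy, 100 * mean(x$accepted)))
  invisible(x)
}

#' Sample an ensemble of well-controlling networks
#'
#' Runs [mcmc_run()] on `n_configs` independent starting graphs and
#' summarizes the final spectral radii (steady-state values, one per
#' configuration).
#'
#' @param generator Either a function `function(seed)` returning a
#'   `net_graph` (a fresh starting graph per configuration) or a single
#'   `net_graph` reused for every configuration.
#' @inheritParams mcmc_run
#' @param n_configs Number of independent configurations.
#' @param seed Master seed; per-configuration graph and run seeds are
#'   spawned from it.
#' @param keep_graphs If `TRUE`, retain the final networks.
#' @return List of class `ensemble_summary`: `finals` (final
#'   `lambda_max` per configuration), `mean`, `sd`, `n_configs`,
#'   optionally `graphs`, and the `config`.
#' @export
sample_ensemble <- function(generator, rho, nu, steps, n_configs, seed,
                            tol = 1e-8, keep_graphs = FALSE) {
  stopifnot(n_configs >= 1)
  set.seed(seed)
  graph_seeds <- sample.int(.Machine$integer.max, n_configs)
  run_seeds <- sample.int(.Machine$integer.max, n_configs)
  finals <- numeric(n_configs)
  graphs <- if (keep_graphs) vector("list", n_configs) else NULL
  for (i in seq_len(n_configs)) {
    g <- if (is.function(generator)) generator(graph_seeds[i]) else generator
    tr <- mcmc_run(g, rho, nu, steps, seed = run_seeds[i], tol = tol)
    finals[i] <- tr$final_energy
    if (keep_graphs) graphs[[i]] <- tr$final_graph
  }
  structure(list(finals = finals, mean = mean(finals), sd = sd(finals),
                 n_configs = as.integer(n_configs), graphs = graphs,
                 config = list(rho = rho, nu = nu, steps = steps,
                               seed = seed)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "ensemble_summary: %d configs (rho=%.2f, nu=%g): mean lambda_max %.3f (sd %.3f)\n",
    x$n_configs, x$config$rho, x$config$nu, x$mean,
    if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' Exact stationary distribution by enumeration (test oracle)
#'
#' Enumerates every subgraph with exactly `E - round(rho * E)` edges,
#' computes its Boltzmann weight `exp(-nu * lambda_max)` and normalizes by
#' the explicit partition function. Feasible only for tiny instances
#' (refuses above `choose(E, n_removed) > 1e5` states); used to verify
#' detailed balance of the sampler.
#'
#' @inheritParams mcmc_run
#' @return Data frame with one row per state: `removed` (comma-separated
#'   sorted removed-edge row indices into `g$edges`), `lambda` and `prob`
#'   (summing to 1). The kept-subgraph complement is implied.
#' @examples
#' p4 <- net_graph(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
#' exact_stationary_distribution(p4, rho = 1 / 3, nu = 1)
#' @export
exact_stationary_distribution <- function(g, rho, nu) {
  stopifnot(inherits(g, "net_graph"), nu >= 0)
  n_rm <- n_removed_edges(g, rho)
  E <- n_edges(g)
  if (n_rm == 0L || n_rm == E)
    stop("degenerate rho: removal must leave both kept and removed edges non-empty")
  if (choose(E, n_rm) > 1e5)
    stop("state space too large to enumerate")
  rm_sets <- combn(E, n_rm)
  lam <- apply(rm_sets, 2, function(rm)
    largest_eigenvalue(.subgraph_keep(g, setdiff(seq_len(E), rm)),
                       method = "dense"))
  w <- exp(-nu * (lam - min(lam))) # shift for numerical stability; cancels in Z
  data.frame(removed = apply(rm_sets, 2, paste, collapse = ","),
             lambda = lam, prob = w / sum(w))
}
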