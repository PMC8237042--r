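# Discrete-time SIS / SIR spreading on a contact graph. Synchronous
# updates: at each step every susceptible node with j infected neighbors
# (counted at the start of the step) becomes infected with probability
# 1 - (1 - beta)^j, and every node infected at the start of the step
# recovers with probability delta (to S for SIS, to the absorbing R for
# SIR). A node infected at step t cannot recover before step t + 1. This
# is the reactive discrete-time process whose epidemic threshold is
# 1 / lambda_max of the adjacency matrix.

#' Epidemic simulation parameters
#'
#' @param beta Per-contact, per-step infection probability in \[0, 1\].
#' @param delta Per-step recovery probability in \[0, 1\].
#' @param initial_infected Number of seed nodes, drawn uniformly at
#'   random and independently per realization.
#' @param seed_nodes Optional explicit vector of 0-based seed node ids
#'   used for every realization; overrides `initial_infected`.
#' @param max_steps Time horizon for SIS; SIR runs to extinction and uses
#'   this only as a safety cap.
#' @param n_realizations Number of independent realizations.
#' @return List of class `epidemic_params`.
#' @examples
#' epidemic_params(beta = 0.1, delta = 0.5, initial_infected = 10)
#' @export
epidemic_params <- function(beta, delta, initial_infected = 10L,
                            seed_nodes = NULL, max_steps = 1000L,
                            n_realizations = 640L) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            is.numeric(delta), length(delta) == 1L, delta >= 0, delta <= 1,
            length(initial_infected) == 1L, initial_infected >= 1,
            max_steps >= 1L, n_realizations >= 1L)
  if (!is.null(seed_nodes))
    stopifnot(length(seed_nodes) >= 1L, all(seed_nodes >= 0),
              !anyDuplicated(seed_nodes))
  structure(list(beta = beta, delta = delta,
                 initial_infected = as.integer(initial_infected),
                 seed_nodes = if (is.null(seed_nodes)) NULL
                              else as.integer(seed_nodes),
                 max_steps = as.integer(max_steps),
                 n_realizations = as.integer(n_realizations)),
            class = "epidemic_params")
}

.seed_matrix <- function(params, n, R) {
  I <- matrix(FALSE, n, R)
  if (is.null(params$seed_nodes)) {
    k <- params$initial_infected
    if (k > n) stop("initial_infected exceeds n_nodes")
    for (r in seq_len(R)) I[sample.int(n, k), r] <- TRUE
  } else {
    if (any(params$seed_nodes >= n))
      stop("seed node id out of range")
    I[params$seed_nodes + 1L, ] <- TRUE
  }
  I
}

.epidemic_core <- function(g, params, seed, model = c("sis", "sir"),
                           record = c("counts", "none")) {
  model <- match.arg(model)
  record <- match.arg(record)
  stopifnot(inherits(g, "net_graph"), inherits(params, "epidemic_params"))
  n <- g$n_nodes
  R <- params$n_realizations
  if (is.null(params$seed_nodes) && params$initial_infected > n)
    stop("initial_infected exceeds n_nodes")
  if (model == "sir" && params$delta <= 0)
    stop("SIR requires delta > 0 to terminate")
  set.seed(seed)
  A <- if (n_edges(g) > 0L)
    Matrix::sparseMatrix(i = c(g$edges[, 1], g$edges[, 2]) + 1L,
                         j = c(g$edges[, 2], g$edges[, 1]) + 1L,
                         x = 1, dims = c(n, n))
  else NULL
  I <- .seed_matrix(params, n, R)
  ever <- I
  Rec <- matrix(FALSE, n, R)
  ext_step <- rep(NA_integer_, R)
  beta <- params$beta; delta <- params$delta
  horizon <- params$max_steps
  traj <- if (record == "counts")
    list(S = matrix(NA_real_, horizon + 1L, R),
         I = matrix(NA_real_, horizon + 1L, R),
         R = matrix(NA_real_, horizon + 1L, R))
  else NULL
  rec_row <- function(t) {
    if (!is.null(traj)) {
      ci <- colSums(I); cr <- colSums(Rec)
      traj$S[t, ] <<- n - ci - cr
      traj$I[t, ] <<- ci
      traj$R[t, ] <<- cr
    }
  }
  rec_row(1L)
  steps_done <- 0L
  for (t in seq_len(horizon)) {
    if (!any(I)) break
    ninf <- if (is.null(A)) matrix(0, n, R) else as.matrix(A %*% (I + 0))
    p_inf <- 1 - (1 - beta)^ninf
    sus <- !I & !Rec
    newI <- sus & (matrix(runif(n * R), n, R) < p_inf)
    recov <- I & (matrix(runif(n * R), n, R) < delta)
    if (model == "sir") Rec <- Rec | recov
    I <- (I & !recov) | newI
    ever <- ever | newI
    steps_done <- t
    rec_row(t + 1L)
    new_ext <- is.na(ext_step) & colSums(I) == 0L
    ext_step[new_ext] <- t
  }
  if (!is.null(traj)) {
    # pad rows after global extinction with the (constant) absorbed counts
    done <- steps_done + 1L
    if (done < horizon + 1L) {
      for (nm in c("S", "I", "R")) {
        traj[[nm]][(done + 1L):(horizon + 1L), ] <-
          matrix(traj[[nm]][done, ], horizon + 1L - done, R, byrow = TRUE)
      }
    }
    if (model == "sis") traj$R <- NULL
  }
  cum <- colSums(ever)
  structure(list(model = model, n_nodes = n,
                 final_S = n - colSums(I) - colSums(Rec),
                 final_I = colSums(I), final_R = colSums(Rec),
                 cumulative_infected = cum,
                 extinction_step = ext_step,
                 mean_cumulative_fraction = mean(cum) / n,
                 trajectories = traj,
                 params = params, seed = seed),
            class = "epidemic_result")
}

#' @export
print.epidemic_result <- function(x, ...) {
  cat(sprintf(
    "epidemic_result (%s): %d realizations on %d nodes; mean cumulative infected fraction %.4f\n",
    toupper(x$model), length(x$cumulative_infected), x$n_nodes,
    x$mean_cumulative_fraction))
  invisible(x)
}

#' Run SIS realizations
#'
#' Synchronous discrete-time susceptible-infected-susceptible dynamics for
#' `max_steps` steps (or until global extinction, after which nothing can
#' change). Cumulative infected counts every node ever infected, seeds
#' included.
#'
#' @param g A `net_graph`.
#' @param params An [epidemic_params()].
#' @param seed Integer RNG seed.
#' @param record `"counts"` stores per-step S/I(/R) count trajectories
#'   (`(max_steps + 1) x n_realizations` matrices), `"none"` skips them.
#' @return An `epidemic_result` with per-realization final compartment
#'   counts, cumulative infected, extinction step (`NA` if still active),
#'   and the aggregate mean cumulative infected fraction.
#' @export
sis_run <- function(g, params, seed, record = "counts") {
  .epidemic_core(g, params, seed, model = "sis", record = record)
}

#' Run SIR realizations
#'
#' As [sis_run()] but recovery moves nodes to the absorbing R state; each
#' realization terminates when no infected nodes remain, at which point
#' the cumulative infected equals the final R count.
#'
#' @inheritParams sis_run
#' @return An `epidemic_result`; `final_I` is all zeros provided the
#'   `max_steps` safety cap was not hit.
#' @export
sir_run <- function(g, params, seed, record = "counts") {
  .epidemic_core(g, params, seed, model = "sir", record = record)
}

#' Mean cumulative infected fraction
#'
#' Average over realizations of (distinct nodes ever infected) / n: the
#' endemicity measure used for tipping-point scans.
#'
#' @inheritParams sis_run
#' @param model `"sis"` or `"sir"`.
#' @return Scalar in \[0, 1\].
#' @export
mean_cumulative_fraction <- function(g, params, seed, model = c("sis", "sir")) {
  .epidemic_core(g, params, seed, model = match.arg(model),
                 record = "none")$mean_cumulative_fraction
}

#' Scan beta/delta ratios for the epidemic tipping point
#'
#' Evaluates the mean cumulative infected fraction on an ascending grid of
#' `beta / delta` ratios at fixed `delta` and reports the smallest grid
#' ratio whose fraction exceeds `threshold` (default 1%). When `g` is a
#' list of graphs the realizations are split evenly across them, so the
#' curve averages over the ensemble.
#'
#' @param g A `net_graph` or a list of them (an ensemble).
#' @param ratios Ascending grid of `beta / delta` ratios; every implied
#'   `beta = ratio * delta` must be at most 1.
#' @param delta Recovery probability (fixed across the scan).
#' @param threshold Tipping threshold on the mean cumulative fraction.
#' @param params An [epidemic_params()]; its `beta` and `delta` are
#'   overridden by the scan.
#' @param seed Integer RNG seed (one sub-seed per grid point).
#' @param model `"sis"` or `"sir"`.
#' @param stop_at_critical If `TRUE`, stop evaluating once the threshold
#'   is first exceeded (remaining grid points are `NA`); the critical
#'   ratio is unaffected as the mean fraction is expected to be
#'   monotone in the ratio.
#' @return List of class `tipping_curve`: data frame `curve` (`ratio`,
#'   `beta`, `mean_cumulative_fraction`), `critical_ratio` (`NA` if the
#'   threshold is never exceeded), `threshold`, `delta`, `model`.
#' @export
tipping_scan <- function(g, ratios, delta = 0.5, threshold = 0.01,
                         params = epidemic_params(beta = 0, delta = delta),
                         seed = 1L, model = c("sis", "sir"),
                         stop_at_critical = FALSE) {
  model <- match.arg(model)
  stopifnot(is.numeric(ratios), length(ratios) >= 1L,
            !is.unsorted(ratios, strictly = TRUE), all(ratios > 0))
  if (any(ratios * delta > 1))
    stop("beta = ratio * delta exceeds 1 at some grid point")
  graphs <- if (inherits(g, "net_graph")) list(g) else g
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, TRUE, "net_graph")))
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(ratios) * length(graphs)),
                      nrow = length(ratios))
  per_graph <- max(1L, params$n_realizations %/% length(graphs))
  fracs <- rep(NA_real_, length(ratios))
  for (i in seq_along(ratios)) {
    b <- ratios[i] * delta
    p <- epidemic_params(beta = b, delta = delta,
                         initial_infected = params$initial_infected,
                         seed_nodes = params$seed_nodes,
                         max_steps = params$max_steps,
                         n_realizations = per_graph)
    vals <- vapply(seq_along(graphs), function(k)
      mean_cumulative_fraction(graphs[[k]], p, sub_seeds[i, k], model),
      numeric(1))
    fracs[i] <- mean(vals)
    if (stop_at_critical && fracs[i] > threshold) break
  }
  crit <- ratios[which(!is.na(fracs) & fracs > threshold)[1]]
  structure(list(curve = data.frame(ratio = ratios, beta = ratios * delta,
                                    mean_cumulative_fraction = fracs),
                 critical_ratio = if (length(crit) && !is.na(crit)) crit else NA_real_,
                 threshold = threshold, delta = delta, model = model),
            class = "tipping_curve")
}

#' @export
print.tipping_curve <- function(x, ...) {
  cat(sprintf("tipping_curve (%s, delta=%.2f): critical beta/delta = %s (threshold %.2f%%)\n",
              toupper(x$model), x$delta,
              if (is.na(x$critical_ratio)) "not reached"
              else format(x$critical_ratio), 100 * x$threshold))
  invisible(x)
}
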