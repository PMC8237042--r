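# Config-driven experiment runners: spectral-radius sweeps, structural
# reports and tipping-point scans across removal strategies, at desk
# scale by default (10 configurations, 200 epidemic realizations) with
# flags to restore the full scale (100 configurations, 640 realizations).

#' Surrogate high-school-scale contact network
#'
#' A planted-partition (stochastic block model) stand-in for a real
#' high-school friendship network of 1062 students: equal-size
#' communities with dense within-group and sparse between-group contact
#' probabilities, calibrated so the expected degree matches
#' `mean_degree` with a fraction `mixing` of each node's contacts
#' crossing community boundaries. Only the network's size is taken from
#' the real data; everything else is a declared, configurable placeholder
#' (see the methods vignette).
#'
#' @param n Number of nodes.
#' @param communities Number of (near-)equal-size communities.
#' @param mean_degree Target expected degree.
#' @param mixing Fraction of a node's expected contacts that are
#'   inter-community.
#' @param seed Integer RNG seed.
#' @return A `net_graph`.
#' @examples
#' g <- surrogate_highschool(seed = 1)
#' g$n_nodes # 1062
#' @export
surrogate_highschool <- function(n = 1062L, communities = 30L,
                                 mean_degree = 8, mixing = 0.1, seed) {
  n <- as.integer(n); communities <- as.integer(communities)
  stopifnot(n >= 2L, communities >= 1L, mean_degree > 0, mean_degree <= n - 1,
            mixing >= 0, mixing < 1)
  sizes <- rep(n %/% communities, communities)
  rem <- n - sum(sizes)
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  s_typ <- max(sizes)
  if (communities == 1L) {
    p_in <- mean_degree / (n - 1)
    p_out <- 0
  } else {
    p_in <- (1 - mixing) * mean_degree / (s_typ - 1)
    p_out <- mixing * mean_degree / (n - s_typ)
  }
  if (p_in > 1)
    stop("infeasible parameters: within-community probability exceeds 1")
  P <- matrix(p_out, communities, communities)
  diag(P) <- p_in
  set.seed(seed)
  from_igraph(igraph::sample_sbm(n, pref.matrix = P, block.sizes = sizes))
}

#' Experiment configuration
#'
#' Bundles the sweep grids and scales shared by the experiment runners.
#' Desk-scale defaults (10 configurations, 200 epidemic realizations)
#' keep full runs in the minutes range; `paper_scale = TRUE` restores
#' 100 configurations and 640 realizations.
#'
#' @param graph Starting-graph spec: `"ba"`, `"rg"`, `"surrogate"`, a
#'   file path to an edge list, or a function `function(seed)` returning
#'   a `net_graph`.
#' @param graph_args Named list of extra arguments for the built-in
#'   generators (e.g. `list(n = 100, m = 10)`).
#' @param strategies Subset of `"random"`, `"wcne"`, `"degree_product"`,
#'   `"degree_cap"`, `"betweenness"`.
#' @param rho_grid Removal-rate grid.
#' @param nu_grid Inverse-genericity grid for the WCNE strategy.
#' @param steps Metropolis steps per WCNE run.
#' @param n_configs Independent starting graphs per cell.
#' @param ratios `beta / delta` grid for tipping scans.
#' @param delta Recovery probability for tipping scans.
#' @param threshold Tipping threshold on the mean cumulative fraction.
#' @param epidemic An [epidemic_params()] template for the scans.
#' @param seed Master seed; every run's sub-seed derives from it.
#' @param paper_scale If `TRUE`, override `n_configs` to 100 and the
#'   epidemic realization count to 640.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(graph = "ba",
                              graph_args = list(),
                              strategies = c("random", "wcne",
                                             "degree_product", "degree_cap"),
                              rho_grid = seq(0.2, 0.9, by = 0.1),
                              nu_grid = c(0, 10, 100, 500, 1000),
                              steps = 11000L,
                              n_configs = 10L,
                              ratios = seq(0.02, 0.5, by = 0.02),
                              delta = 0.5,
                              threshold = 0.01,
                              epidemic = epidemic_params(beta = 0, delta = delta,
                                                         initial_infected = 10L,
                                                         max_steps = 1000L,
                                                         n_realizations = 200L),
                              seed = 1L,
                              paper_scale = FALSE) {
  if (length(strategies) > 0L)
    strategies <- match.arg(strategies,
                            c("random", "wcne", "degree_product",
                              "degree_cap", "betweenness"),
                            several.ok = TRUE)
  if (paper_scale) {
    n_configs <- 100L
    epidemic$n_realizations <- 640L
  }
  cfg <- list(graph = graph, graph_args = graph_args,
              strategies = strategies, rho_grid = rho_grid,
              nu_grid = nu_grid, steps = as.integer(steps),
              n_configs = as.integer(n_configs), ratios = ratios,
              delta = delta, threshold = threshold, epidemic = epidemic,
              seed = as.integer(seed), paper_scale = paper_scale)
  class(cfg) <- "experiment_config"
  cfg
}

# md5 of the serialized config: provenance tag carried on every output row
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "hash")], f)
  unname(tools::md5sum(f))
}

.graph_factory <- function(config) {
  ga <- config$graph_args
  if (is.function(config$graph)) return(config$graph)
  switch(config$graph,
         ba = function(seed) do.call(generate_ba, c(list(
           n = ga$n %||% 100L, m = ga$m %||% 10L, seed = seed))),
         rg = function(seed) generate_rg(
           n = ga$n %||% 100L,
           radius = ga$radius %||% rg_radius_for_degree(ga$n %||% 100L, 18),
           seed = seed),
         surrogate = function(seed) do.call(surrogate_highschool, c(
           list(seed = seed),
           ga[intersect(names(ga),
                        c("n", "communities", "mean_degree", "mixing"))])),
         { # file path: fixed graph, seed ignored
           path <- config$graph
           g <- read_edge_list(path)
           function(seed) g
         })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply one removal strategy at rate rho; wcne uses the Metropolis sampler
apply_strategy <- function(g, strategy, rho, seed, nu = 1000,
                           steps = 11000L) {
  switch(strategy,
         random = random_removal(g, rho, seed),
         wcne = mcmc_run(g, rho, nu, steps, seed)$final_graph,
         degree_product = degree_product_removal(g, rho, seed),
         degree_cap = degree_cap_for_rate(g, rho, seed),
         betweenness = edge_betweenness_removal(g, rho, seed),
         stop("unknown strategy: ", strategy))
}

.sub_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}

#' Spectral-radius sweep across strategies, removal rates and genericities
#'
#' For every combination of strategy and removal rate (and, for the WCNE
#' strategy, every `nu` in the grid) draws `n_configs` independent
#' starting graphs, applies the removal, and summarizes the resulting
#' largest eigenvalues.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; if given, the table is written to
#'   `lambda_sweep.csv` there.
#' @return Data frame with columns `strategy`, `rho`, `nu`,
#'   `mean_lambda`, `sd_lambda`, `n_configs`, `sub_seed`, `config_hash`.
#' @export
run_lambda_sweep <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  factory <- .graph_factory(config)
  cells <- list()
  for (strategy in config$strategies) {
    nus <- if (strategy == "wcne") config$nu_grid else NA_real_
    for (nu in nus)
      for (rho in config$rho_grid)
        cells[[length(cells) + 1L]] <- list(strategy = strategy,
                                            rho = rho, nu = nu)
  }
  cell_seeds <- .sub_seeds(config$seed, length(cells))
  rows <- lapply(seq_along(cells), function(ci) {
    cell <- cells[[ci]]
    seeds <- .sub_seeds(cell_seeds[ci], 2L * config$n_configs)
    lam <- vapply(seq_len(config$n_configs), function(i) {
      g <- factory(seeds[i])
      red <- if (cell$strategy == "wcne")
        apply_strategy(g, "wcne", cell$rho, seeds[config$n_configs + i],
                       nu = cell$nu, steps = config$steps)
      else
        apply_strategy(g, cell$strategy, cell$rho,
                       seeds[config$n_configs + i])
      largest_eigenvalue(red)
    }, numeric(1))
    data.frame(strategy = cell$strategy, rho = cell$rho, nu = cell$nu,
               mean_lambda = mean(lam),
               sd_lambda = if (length(lam) > 1) sd(lam) else 0,
               n_configs = config$n_configs, sub_seed = cell_seeds[ci],
               config_hash = hash)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "lambda_sweep.csv"),
              row.names = FALSE)
  }
  out
}

#' Structural report: degree histograms, components, giant size
#'
#' Computes, per strategy and removal rate, the ensemble-mean component
#' count and giant-component size, plus the pooled degree histogram of
#' the reduced networks.
#'
#' @inheritParams run_lambda_sweep
#' @param nu Inverse genericity used for the WCNE strategy.
#' @return List of class `structure_report` with data frames `metrics`
#'   (`strategy`, `rho`, `mean_components`, `mean_giant_size`,
#'   `n_configs`, `sub_seed`, `config_hash`) and `degree_distribution`
#'   (`strategy`, `rho`, `degree`, `mean_count`). Written as
#'   `structure_metrics.csv` / `degree_distribution.csv` if `out_dir` is
#'   given.
#' @export
run_structure_report <- function(config, nu = 1000, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  factory <- .graph_factory(config)
  cells <- expand.grid(strategy = config$strategies, rho = config$rho_grid,
                       stringsAsFactors = FALSE)
  cell_seeds <- .sub_seeds(config$seed, nrow(cells))
  metrics <- list(); dd <- list()
  for (ci in seq_len(nrow(cells))) {
    strategy <- cells$strategy[ci]; rho <- cells$rho[ci]
    seeds <- .sub_seeds(cell_seeds[ci], 2L * config$n_configs)
    ncomp <- numeric(config$n_configs)
    giant <- numeric(config$n_configs)
    degtab <- NULL
    for (i in seq_len(config$n_configs)) {
      g <- factory(seeds[i])
      red <- apply_strategy(g, strategy, rho, seeds[config$n_configs + i],
                            nu = nu, steps = config$steps)
      cs <- component_summary(red)
      ncomp[i] <- cs$n_components
      giant[i] <- cs$giant_size
      h <- degree_histogram(red)
      degtab <- if (is.null(degtab)) setNames(h$count, h$degree) else {
        all_deg <- union(names(degtab), as.character(h$degree))
        out <- setNames(numeric(length(all_deg)), all_deg)
        out[names(degtab)] <- degtab
        out[as.character(h$degree)] <- out[as.character(h$degree)] + h$count
        out
      }
    }
    metrics[[ci]] <- data.frame(strategy = strategy, rho = rho,
                                mean_components = mean(ncomp),
                                mean_giant_size = mean(giant),
                                n_configs = config$n_configs,
                                sub_seed = cell_seeds[ci],
                                config_hash = hash)
    deg <- as.integer(names(degtab))
    o <- order(deg)
    dd[[ci]] <- data.frame(strategy = strategy, rho = rho,
                           degree = deg[o],
                           mean_count = unname(degtab[o]) / config$n_configs)
  }
  res <- list(metrics = do.call(rbind, metrics),
              degree_distribution = do.call(rbind, dd))
  class(res) <- "structure_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$metrics, file.path(out_dir, "structure_metrics.csv"),
              row.names = FALSE)
    write.csv(res$degree_distribution,
              file.path(out_dir, "degree_distribution.csv"),
              row.names = FALSE)
  }
  res
}

#' Tipping-point report across strategies and removal rates
#'
#' Runs [tipping_scan()] on reduced networks per strategy and removal
#' rate and tabulates the critical `beta / delta` ratios.
#'
#' @inheritParams run_structure_report
#' @param model `"sis"` or `"sir"`.
#' @param n_graphs Reduced networks per cell over which realizations are
#'   split (kept small: each WCNE sample is a full MCMC run).
#' @param stop_at_critical Passed to [tipping_scan()].
#' @return Data frame with columns `strategy`, `rho`, `critical_ratio`,
#'   `threshold`, `n_realizations`, `sub_seed`, `config_hash`; written to
#'   `tipping_report.csv` if `out_dir` is given.
#' @export
run_tipping_report <- function(config, nu = 1000, model = "sis",
                               n_graphs = 1L, stop_at_critical = FALSE,
                               out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  factory <- .graph_factory(config)
  if (length(config$strategies) == 0L) {
    return(data.frame(strategy = character(0), rho = numeric(0),
                      critical_ratio = numeric(0), threshold = numeric(0),
                      n_realizations = integer(0), sub_seed = integer(0),
                      config_hash = character(0)))
  }
  cells <- expand.grid(strategy = config$strategies, rho = config$rho_grid,
                       stringsAsFactors = FALSE)
  cell_seeds <- .sub_seeds(config$seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    strategy <- cells$strategy[ci]; rho <- cells$rho[ci]
    seeds <- .sub_seeds(cell_seeds[ci], 2L * n_graphs + 1L)
    graphs <- lapply(seq_len(n_graphs), function(i) {
      g <- factory(seeds[i])
      apply_strategy(g, strategy, rho, seeds[n_graphs + i], nu = nu,
                     steps = config$steps)
    })
    tc <- tipping_scan(graphs, config$ratios, delta = config$delta,
                       threshold = config$threshold,
                       params = config$epidemic,
                       seed = seeds[2L * n_graphs + 1L], model = model,
                       stop_at_critical = stop_at_critical)
    data.frame(strategy = strategy, rho = rho,
               critical_ratio = tc$critical_ratio,
               threshold = config$threshold,
               n_realizations = config$epidemic$n_realizations,
               sub_seed = cell_seeds[ci], config_hash = hash)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "tipping_report.csv"),
              row.names = FALSE)
  }
  out
}
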