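test_that("beta = 0 never spreads: cumulative infected equals the seeds", {
  g <- generate_ba(100, 10, seed = 1)
  p <- epidemic_params(beta = 0, delta = 0.3, initial_infected = 10,
                       max_steps = 50, n_realizations = 30)
  for (run in list(sis_run(g, p, seed = 1), sir_run(g, p, seed = 2))) {
    expect_true(all(run$cumulative_infected == 10))
  }
  # SIR terminates with final R = seeds
  res <- sir_run(g, p, seed = 3)
  expect_true(all(res$final_I == 0))
  expect_true(all(res$final_R == 10))

  # exact fraction on the surrogate scale
  sg <- surrogate_highschool(seed = 4)
  p2 <- epidemic_params(beta = 0, delta = 0.5, initial_infected = 10,
                        max_steps = 5, n_realizations = 5)
  expect_equal(mean_cumulative_fraction(sg, p2, seed = 1), 10 / 1062)
})

test_that("compartment counts are conserved at every step", {
  g <- random_gnp(40, 0.2, seed = 2)
  p <- epidemic_params(beta = 0.3, delta = 0.4, initial_infected = 5,
                       max_steps = 60, n_realizations = 25)
  sis <- sis_run(g, p, seed = 9)
  expect_true(all(sis$trajectories$S + sis$trajectories$I == 40))
  sir <- sir_run(g, p, seed = 9)
  expect_true(all(sir$trajectories$S + sir$trajectories$I +
                    sir$trajectories$R == 40))
  # cumulative infected is at least the seed count and at most n
  for (res in list(sis, sir)) {
    expect_true(all(res$cumulative_infected >= 5))
    expect_true(all(res$cumulative_infected <= 40))
  }
  # SIR cumulative infected equals final R once extinct
  expect_true(all(sir$cumulative_infected == sir$final_R))
})

test_that("single-step and deterministic cascades match analytic results", {
  # isolated seed with certain recovery: extinct after one step
  iso <- net_graph(3, rbind(c(1, 2)))
  p <- epidemic_params(beta = 0.7, delta = 1, seed_nodes = 0,
                       max_steps = 10, n_realizations = 20)
  res <- sis_run(iso, p, seed = 1)
  expect_true(all(res$cumulative_infected == 1))
  expect_true(all(res$extinction_step == 1))

  # single edge, beta = 0.5, delta = 1, one step: E[cumulative] = 1.5
  edge <- net_graph(2, rbind(c(0, 1)))
  p2 <- epidemic_params(beta = 0.5, delta = 1, seed_nodes = 0,
                        max_steps = 1, n_realizations = 4000)
  res2 <- sis_run(edge, p2, seed = 2, record = "none")
  expect_equal(mean(res2$cumulative_infected), 1.5, tolerance = 0.05)

  # star center seeded with beta = delta = 1: full deterministic cascade
  st <- star_graph(6)
  p3 <- epidemic_params(beta = 1, delta = 1, seed_nodes = 0,
                        max_steps = 100, n_realizations = 8)
  res3 <- sir_run(st, p3, seed = 3)
  expect_true(all(res3$cumulative_infected == 7))
  # connected graph, beta = delta = 1, SIR reaches everyone
  expect_equal(mean_cumulative_fraction(complete_graph(6),
                                        epidemic_params(1, 1, 1,
                                                        n_realizations = 10),
                                        seed = 4, model = "sir"), 1)
})

test_that("K3 SIR final-size distribution matches exhaustive enumeration", {
  k3 <- complete_graph(3)
  exact <- sir_final_size_exact(k3, beta = 0.5, seed_nodes = 0)
  expect_equal(sum(exact), 1, tolerance = 1e-12)
  expect_equal(unname(exact[c("1", "2", "3")]), c(0.25, 0.25, 0.5))

  p <- epidemic_params(beta = 0.5, delta = 1, seed_nodes = 0,
                       max_steps = 50, n_realizations = 3000)
  res <- sir_run(k3, p, seed = 5, record = "none")
  counts <- table(factor(res$cumulative_infected, levels = 1:3))
  expect_gt(chisq.test(as.numeric(counts), p = unname(exact))$p.value, 0.001)
})

test_that("mean cumulative fraction is monotone in beta (paired seeds)", {
  g <- generate_ba(100, 10, seed = 6)
  fr <- vapply(c(0.02, 0.05, 0.1), function(b)
    mean_cumulative_fraction(g, epidemic_params(b, 0.5, 5, max_steps = 200,
                                                n_realizations = 100),
                             seed = 77), numeric(1))
  expect_true(all(diff(fr) > -0.02))
})

test_that("spreading tracks the spectral threshold on BA graphs", {
  g <- generate_ba(100, 10, seed = 8)
  tau <- epidemic_threshold(g)
  delta <- 0.5
  p_sub <- epidemic_params(0.5 * tau * delta, delta, initial_infected = 1,
                           max_steps = 1000, n_realizations = 200)
  p_sup <- epidemic_params(3 * tau * delta, delta, initial_infected = 1,
                           max_steps = 1000, n_realizations = 200)
  sub <- mean_cumulative_fraction(g, p_sub, seed = 21)
  sup <- mean_cumulative_fraction(g, p_sup, seed = 22)
  expect_lte(sub, 3 * 1 / 100)
  expect_gt(sup, 10 * 1 / 100)
})

test_that("tipping scan finds the critical ratio and flags unreachable thresholds", {
  # empty graph: never exceeds the threshold beyond the seeds
  tc <- tipping_scan(net_graph(200), ratios = c(0.1, 0.2), delta = 0.5,
                     params = epidemic_params(0, 0.5, initial_infected = 1,
                                              max_steps = 20,
                                              n_realizations = 10),
                     seed = 1)
  expect_true(is.na(tc$critical_ratio))

  # complete graph K50: critical ratio within a factor ~2 of 1/49
  k50 <- complete_graph(50)
  grid <- c(1 / 49 / 4, 1 / 49 / 2, 1 / 49, 2 / 49, 4 / 49)
  tc2 <- tipping_scan(k50, ratios = grid, delta = 0.5, threshold = 0.05,
                      params = epidemic_params(0, 0.5, initial_infected = 1,
                                               max_steps = 1000,
                                               n_realizations = 150),
                      seed = 2)
  expect_false(is.na(tc2$critical_ratio))
  expect_lte(tc2$critical_ratio, 2 / 49 + 1e-12)
  expect_gte(tc2$critical_ratio, 1 / 49 / 2 - 1e-12)

  # beta > 1 on the grid is a parameter error
  expect_error(tipping_scan(k50, ratios = c(0.5, 3), delta = 0.5),
               "exceeds 1")

  # stop_at_critical leaves the tail unevaluated but the same critical ratio
  tc3 <- tipping_scan(k50, ratios = grid, delta = 0.5, threshold = 0.05,
                      params = epidemic_params(0, 0.5, initial_infected = 1,
                                               max_steps = 1000,
                                               n_realizations = 150),
                      seed = 2, stop_at_critical = TRUE)
  expect_equal(tc3$critical_ratio, tc2$critical_ratio)
})
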