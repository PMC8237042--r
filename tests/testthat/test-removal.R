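test_that("all rate-parameterized strategies remove exactly round(rho*E) edges", {
  g <- random_gnp(40, 0.25, seed = 1)
  E <- n_edges(g)
  for (rho in c(0.21, 0.4, 0.55, 0.8)) {
    expected_kept <- E - floor(rho * E + 0.5)
    for (fn in list(random_removal, degree_product_removal,
                    degree_cap_for_rate, edge_betweenness_removal)) {
      red <- fn(g, rho, 11)
      expect_equal(n_edges(red), expected_kept)
      expect_equal(red$n_nodes, g$n_nodes)
      # subgraph of the input
      expect_true(all(interaction(red$edges[, 1], red$edges[, 2]) %in%
                        interaction(g$edges[, 1], g$edges[, 2])))
    }
  }
  expect_error(random_removal(g, 0, 1), "rho")
  expect_error(random_removal(g, 1.2, 1), "rho")
})

test_that("strategies are deterministic given a seed", {
  g <- random_gnp(30, 0.3, seed = 2)
  for (fn in list(random_removal, degree_product_removal,
                  degree_cap_for_rate, edge_betweenness_removal)) {
    expect_identical(fn(g, 0.5, 42)$edges, fn(g, 0.5, 42)$edges)
  }
  expect_identical(degree_cap_removal(g, 3, 42)$edges,
                   degree_cap_removal(g, 3, 42)$edges)
})

test_that("random removal draws retained sets uniformly", {
  # 4 edges, rho = 0.5: each of the C(4,2)=6 retained pairs equally likely
  g <- net_graph(4, rbind(c(0, 1), c(1, 2), c(2, 3), c(0, 3)))
  counts <- table(vapply(1:6000, function(s)
    paste(random_removal(g, 0.5, s)$edges, collapse = ","), ""))
  expect_equal(length(counts), 6L)
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("degree-product removal targets max-product edges with random ties", {
  # path a-b-c-d: products (2,4,2) force the middle edge out
  red <- degree_product_removal(path_graph(4), rho = 1 / 3, seed = 5)
  expect_equal(red$edges, cbind(c(0L, 2L), c(1L, 3L)))

  # star K_{1,3}: all products tie, each leaf edge removed ~1/3 of the time
  leaves <- vapply(1:3000, function(s) {
    red <- degree_product_removal(star_graph(3), rho = 1 / 3, seed = s)
    setdiff(1:3, red$edges[, 2])
  }, numeric(1))
  expect_gt(chisq.test(table(leaves))$p.value, 0.001)
})

test_that("degree-product removal homogenizes degrees relative to random", {
  var_dp <- var_rand <- numeric(20)
  for (s in 1:20) {
    g <- generate_ba(100, 10, seed = s)
    var_dp[s] <- var(degrees(degree_product_removal(g, 0.8, seed = s + 100)))
    var_rand[s] <- var(degrees(random_removal(g, 0.8, seed = s + 100)))
  }
  expect_lt(mean(var_dp), mean(var_rand))
})

test_that("degree cap enforces the cap against current degrees", {
  # node of degree 5 with k_max = 3 loses exactly 2 links
  g <- star_graph(5)
  red <- degree_cap_removal(g, 3, seed = 1)
  expect_equal(n_edges(red), 3L)
  expect_lte(max(degrees(red)), 3L)

  # cap at or above max degree: unchanged
  g2 <- random_gnp(20, 0.3, seed = 3)
  expect_identical(degree_cap_removal(g2, max(degrees(g2)), seed = 1)$edges,
                   g2$edges)

  # K5 with k_max=3: final degrees all <= 3, for any seed and order
  for (s in 1:25) {
    red <- degree_cap_removal(complete_graph(5), 3, seed = s)
    expect_lte(max(degrees(red)), 3L)
    redr <- degree_cap_removal(complete_graph(5), 3, seed = s,
                               order = "random")
    expect_lte(max(degrees(redr)), 3L)
  }
})

test_that("K5 cap removal count distribution matches an independent sequential simulation", {
  # independent brute-force of the sequential rule: process nodes in order,
  # remove random excess links against current degrees
  brute <- function(seed) {
    set.seed(seed)
    edges <- t(combn(1:5, 2))
    alive <- rep(TRUE, nrow(edges))
    for (node in 1:5) {
      mine <- which(alive & (edges[, 1] == node | edges[, 2] == node))
      excess <- length(mine) - 3L
      if (excess > 0L) alive[mine[sample.int(length(mine), excess)]] <- FALSE
    }
    sum(!alive)
  }
  n_rm_pkg <- vapply(1:400, function(s)
    10L - n_edges(degree_cap_removal(complete_graph(5), 3, seed = s)),
    integer(1))
  n_rm_brute <- vapply(401:800, function(s) brute(s), integer(1))
  tb <- table(factor(n_rm_pkg, levels = 0:10),
              factor(n_rm_brute, levels = 0:10))
  lv <- union(names(which(rowSums(tb) > 0)), names(which(colSums(tb) > 0)))
  m <- cbind(table(factor(n_rm_pkg, levels = lv)),
             table(factor(n_rm_brute, levels = lv)))
  expect_gt(suppressWarnings(chisq.test(m)$p.value), 0.001)
})

test_that("rate-matched degree cap hits the exact edge count", {
  # K5, rho = 0.4: exactly 4 of 10 edges removed
  red <- degree_cap_for_rate(complete_graph(5), 0.4, seed = 2)
  expect_equal(n_edges(red), 6L)

  # rho -> 0 limit: zero-edge target, cap stays at max degree, no change
  g <- random_gnp(30, 0.3, seed = 4)
  red <- degree_cap_for_rate(g, 0.5 / n_edges(g) * 0.9, seed = 5)
  expect_equal(attr(red, "k_max"), max(degrees(g)))
  expect_identical(red$edges, g$edges)
  # at moderate rho the selected cap binds: it is the smallest cap whose
  # pass does not overshoot the removal target
  red2 <- degree_cap_for_rate(g, 0.3, seed = 5)
  k2 <- attr(red2, "k_max")
  cap_removed <- function(k) n_edges(g) -
    n_edges(degree_cap_removal(g, k, seed = 5))
  target <- floor(0.3 * n_edges(g) + 0.5)
  expect_lte(cap_removed(k2), target)
  if (k2 > 0) expect_gt(cap_removed(k2 - 1L), target)

  # property: exact retained count across random inputs
  for (s in 1:25) {
    g <- random_gnp(sample(10:40, 1), runif(1, 0.15, 0.5), seed = s)
    rho <- runif(1, 0.05, 0.95)
    if (n_edges(g) < 3) next
    red <- degree_cap_for_rate(g, rho, seed = s)
    expect_equal(n_edges(red), n_edges(g) - floor(rho * n_edges(g) + 0.5))
  }
})

test_that("edge-betweenness removal takes bridges first and underperforms random", {
  # two triangles joined by a bridge: the bridge goes first
  g <- net_graph(6, rbind(c(0, 1), c(1, 2), c(0, 2),
                          c(3, 4), c(4, 5), c(3, 5), c(2, 3)))
  red <- edge_betweenness_removal(g, rho = 1 / 7, seed = 1)
  expect_false(any(red$edges[, 1] == 2 & red$edges[, 2] == 3))
  expect_equal(n_edges(red), 6L)

  # on BA networks it reduces lambda_max less than random removal
  lam_eb <- lam_rand <- numeric(20)
  for (s in 1:20) {
    g <- generate_ba(100, 10, seed = s)
    lam_eb[s] <- largest_eigenvalue(edge_betweenness_removal(g, 0.4, seed = s))
    lam_rand[s] <- largest_eigenvalue(random_removal(g, 0.4, seed = s))
  }
  expect_gte(mean(lam_eb), mean(lam_rand))
})
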