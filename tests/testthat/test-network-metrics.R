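triangle_graph <- function() {
  ps <- point_set(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                  model = "EXTERNAL")
  build_geometric_graph(ps, 1)
}

path3_graph <- function() {
  build_geometric_graph(point_set(cbind(0:2, 0), model = "EXTERNAL"), 1)
}

test_that("degree distribution identities hold", {
  tg <- triangle_graph()
  dd <- degree_distribution(tg)
  expect_equal(dd$p_k, data.frame(k = 2L, p_k = 1))
  expect_equal(dd$k_mean, 2)

  dp <- degree_distribution(path3_graph())
  expect_equal(dp$p_k, data.frame(k = 1:2, p_k = c(2 / 3, 1 / 3)))

  for (seed in 1:3) {
    ps <- random_point_set(90, seed = seed)
    n <- n_points(ps)
    dd <- degree_distribution(build_geometric_graph(ps, 2.2))
    expect_equal(sum(dd$p_k$p_k), 1)
    expect_equal(dd$k_mean, 2 * dd$L / n)
    expect_equal(dd$k_mean, dd$density * (n - 1))
  }
})

test_that("clustering matches the brute-force triangle count", {
  expect_equal(mean_clustering(triangle_graph()), 1)
  expect_equal(mean_clustering(path3_graph()), 0)
  expect_equal(mean_clustering(build_geometric_graph(generate_vicsek(4), 1)),
               0)
  g7 <- build_geometric_graph(generate_hexagonal(7), 1)
  expect_equal(mean_clustering(g7), (6 / 15 + 6 * 2 / 3) / 7,
               tolerance = 1e-12)
  for (seed in 1:4) {
    ps <- random_point_set(70, seed = seed)
    g <- build_geometric_graph(ps, 2.5)
    expect_equal(mean_clustering(g), brute_clustering(g$edges, g$n),
                 tolerance = 1e-12)
  }
})

test_that("path stats match enumerated values and the all-pairs oracle", {
  ps <- path_stats(path3_graph())
  expect_equal(ps$l_mean, 4 / 3)
  expect_equal(ps$e_mean, 5 / 6)
  expect_equal(ps$n_disconnected_pairs, 0)

  iso <- point_set(rbind(c(0, 0), c(10, 0)), model = "EXTERNAL")
  pi2 <- path_stats(build_geometric_graph(iso, 1))
  expect_equal(pi2$e_mean, 0)
  expect_true(is.nan(pi2$l_mean))
  expect_equal(pi2$n_disconnected_pairs, 1)

  for (seed in 1:4) {
    ps <- random_point_set(60, seed = seed + 10)
    g <- build_geometric_graph(ps, 2)
    got <- path_stats(g)
    want <- brute_path_stats(g$edges, g$n)
    expect_equal(got$l_mean, want$l_mean, tolerance = 1e-12)
    expect_equal(got$e_mean, want$e_mean, tolerance = 1e-12)
    expect_equal(got$n_disconnected_pairs, want$n_disconnected_pairs)
  }
})

test_that("sampled path stats agree with exact within sampling error", {
  g <- build_geometric_graph(generate_hexagonal(1000), 1)
  exact <- path_stats(g)
  hits <- 0
  for (seed in 1:10) {
    sm <- path_stats(g, mode = "sampled", n_sources = 200, seed = seed)
    if (abs(sm$e_mean - exact$e_mean) <= 3 * sm$e_se) hits <- hits + 1
  }
  expect_gte(hits, 9)
  expect_error(path_stats(g, mode = "sampled", n_sources = 2000),
               "exceeds")
})

test_that("center-perimeter ratio is 1 on a straight chain", {
  chain <- point_set(cbind(0:9, 0), model = "EXTERNAL")
  cp <- center_perimeter(build_geometric_graph(chain, 1))
  expect_equal(cp$l0_max, 9)
  expect_equal(cp$R, 9)
  expect_equal(cp$eta_max, 1)
  expect_equal(cp$eta_max_strict, 1)
})

test_that("center-perimeter errors when the perimeter is unreachable", {
  iso <- point_set(rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0)),
                   model = "EXTERNAL")
  expect_error(center_perimeter(build_geometric_graph(iso, 1)),
               "components")
})

test_that("hop counts respect the euclidean lower bound l_ij >= d_ij / r", {
  ps <- generate_ba(250, seed = 5)$points
  for (r in c(1, 2)) {
    g <- build_geometric_graph(ps, r)
    d_hop <- igraph::distances(g$graph, algorithm = "unweighted")
    d_euc <- as.matrix(dist(ps$coords))
    fin <- is.finite(d_hop)
    expect_true(all(d_hop[fin] >= d_euc[fin] / (r * (1 + 1e-9)) - 1e-9))
  }
  cp <- center_perimeter(build_geometric_graph(ps, 1))
  expect_gte(cp$eta_max_strict, 1 - 1e-9)
})

test_that("network_summary panel is internally consistent", {
  ps <- generate_dla(300, seed = 12)$points
  ns <- network_summary(build_geometric_graph(ps, 1.5))
  expect_equal(ns$k_mean, 2 * ns$L / ns$N)
  expect_equal(sum(ns$p_k$p_k), 1)
  expect_gte(ns$E_mean, 0)
  expect_lte(ns$E_mean, 1)
  expect_equal(ns$n_components, 1)

  nss <- network_summary(build_geometric_graph(ps, 1.5),
                         path_mode = "sampled", n_sources = 100,
                         seed = 1)
  expect_lt(abs(nss$E_mean - ns$E_mean), 5 * nss$e_se + 1e-12)
})
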