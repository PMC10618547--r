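test_that("Vicsek iterates have the IFS point counts and tree contact graphs", {
  v1 <- generate_vicsek(1)
  expect_equal(n_points(v1), 1L)
  expect_equal(unname(v1$coords[1, ]), c(0, 0))

  v2 <- generate_vicsek(2)
  expect_equal(n_points(v2), 5L)
  # origin plus the four unit axis points, in radius-then-angle order
  expect_equal(unname(v2$coords[1, ]), c(0, 0))
  expect_setequal(round(v2$coords[, 1] + 10 * v2$coords[, 2]),
                  c(0, 1, 10, -1, -10))
  expect_equal(edge_count(build_geometric_graph(v2, 1)), 4L)

  v3 <- generate_vicsek(3)
  expect_equal(n_points(v3), 25L)
  g3 <- build_geometric_graph(v3, 1)
  expect_equal(edge_count(g3), 24L)
  expect_equal(mean_clustering(g3), 0)

  for (it in 2:5)
    expect_equal(n_points(generate_vicsek(it)), 5L^(it - 1))
  expect_error(generate_vicsek(9, max_points = 1e4), "max_points")
})

test_that("Hexaflake iterates have 7^(n-1) points at unit spacing", {
  h1 <- generate_hexaflake(1)
  expect_equal(n_points(h1), 1L)
  expect_equal(unname(h1$coords[1, ]), c(0, 0))

  h2 <- generate_hexaflake(2)
  expect_equal(n_points(h2), 7L)
  expect_equal(edge_count(build_geometric_graph(h2, 1)), 12L)

  for (it in 2:4) {
    h <- generate_hexaflake(it)
    expect_equal(n_points(h), 7L^(it - 1))
    expect_equal(min_separation(h), 1, tolerance = 1e-12)
  }
})

test_that("hexagonal patch has the expected first-ring geometry", {
  hx <- generate_hexagonal(7)
  expect_equal(n_points(hx), 7L)
  expect_equal(unname(hx$coords[1, ]), c(0, 0))
  r <- sqrt(rowSums(hx$coords^2))
  expect_equal(r, c(0, rep(1, 6)), tolerance = 1e-12)
  g <- build_geometric_graph(hx, 1)
  expect_equal(edge_count(g), 12L)
  expect_equal(sort(degree_sequence(g), decreasing = TRUE),
               c(6L, rep(3L, 6)))
})

test_that("kagome lattice has coordination 4 in the interior", {
  kg <- generate_kagome(400)
  expect_equal(min_separation(kg), 1, tolerance = 1e-12)
  k <- degree_sequence(build_geometric_graph(kg, 1))
  r <- sqrt(rowSums(kg$coords^2))
  interior <- r < max(r) - 2
  expect_true(all(k[interior] == 4L))
  expect_lte(max(k), 4L)
})

test_that("DLA growth satisfies the contact and connectivity contracts", {
  d1 <- generate_dla(1, seed = 5)
  expect_equal(n_points(d1$points), 1L)
  expect_equal(unname(d1$points$coords[1, ]), c(0, 0))
  expect_equal(nrow(d1$history), 1L)

  run <- generate_dla(100, seed = 7)
  co <- run$points$coords
  expect_equal(unname(co[1, ]), c(0, 0))
  # brute-force hard-disk check
  dm <- as.matrix(dist(co))
  diag(dm) <- Inf
  expect_gte(min(dm), 1 - 1e-9)
  # every particle touches an earlier one at unit distance
  for (i in 2:100)
    expect_lte(abs(min(dm[i, 1:(i - 1)]) - 1), 1e-9)
  g <- build_geometric_graph(run$points, 1)
  expect_gte(edge_count(g), 99L)
  expect_equal(igraph::count_components(g$graph), 1)
})

test_that("BA growth sticks the first particle at unit distance", {
  run <- generate_ba(2, seed = 11)
  expect_equal(sqrt(sum(run$points$coords[2, ]^2)), 1, tolerance = 1e-9)

  run100 <- generate_ba(100, seed = 11)
  dm <- as.matrix(dist(run100$points$coords))
  diag(dm) <- Inf
  expect_gte(min(dm), 1 - 1e-9)
  g <- build_geometric_graph(run100$points, 1)
  expect_equal(igraph::count_components(g$graph), 1)
})

test_that("aggregation is bit-reproducible under a fixed seed", {
  a <- generate_dla(150, seed = 42)
  b <- generate_dla(150, seed = 42)
  expect_identical(a$points$coords, b$points$coords)
  expect_identical(a$history, b$history)
  expect_false(identical(a$points$coords,
                         generate_dla(150, seed = 43)$points$coords))
  x <- generate_ba(150, seed = 42)
  y <- generate_ba(150, seed = 42)
  expect_identical(x$points$coords, y$points$coords)
})

test_that("growth history records every particle early, every 10th late", {
  run <- generate_dla(1205, seed = 2)
  h <- run$history
  expect_true(all(diff(h$n) > 0))
  expect_true(all(1:1000 %in% h$n))
  expect_true(all(h$n[h$n > 1000] %% 10 == 0 | h$n[h$n > 1000] == 1205))
  expect_true(1205 %in% h$n)
  expect_true(all(h$rg >= 0))
})

test_that("radial truncation keeps the center, connectivity and radius order", {
  v <- generate_vicsek(5)  # 625-point tree
  expect_identical(truncate_radial(v, n_points(v))$coords, v$coords)
  t1 <- truncate_radial(v, 1)
  expect_equal(unname(t1$coords), matrix(c(0, 0), 1))

  t300 <- truncate_radial(v, 300)
  expect_equal(n_points(t300), 300L)
  expect_equal(unname(t300$coords[1, ]), c(0, 0))
  g <- build_geometric_graph(t300, 1)
  expect_equal(igraph::count_components(g$graph), 1)
  expect_equal(edge_count(g), 299L)  # subtree of a tree

  expect_error(truncate_radial(v, 626), "between 1 and")
  two <- point_set(rbind(c(0, 0), c(1, 0), c(9, 0), c(10, 0)),
                   model = "EXTERNAL")
  expect_error(truncate_radial(two, 3), "disconnected")
})

test_that("contact graphs of all generators respect the kissing bound", {
  systems <- list(generate_dla(300, seed = 1)$points,
                  generate_ba(300, seed = 1)$points,
                  generate_vicsek(4),
                  generate_hexaflake(3),
                  generate_hexagonal(300),
                  generate_kagome(300))
  for (ps in systems) {
    expect_gte(min_separation(ps), 1 - 1e-9)
    g <- build_geometric_graph(ps, 1)
    expect_lte(max(degree_sequence(g)), 6L)
    expect_equal(igraph::count_components(g$graph), 1)
    validate_point_set(ps)
  }
})

test_that("point_set constructor validates its inputs", {
  expect_error(point_set(cbind(1, 2, 3)), "two columns")
  expect_error(point_set(rbind(c(5, 5), c(6, 5))), "origin")
  expect_error(point_set(rbind(c(0, 0), c(NaN, 1))), "finite")
  expect_error(growth_history(c(1, 1), c(0, 0)), "increasing")
  expect_error(growth_history(1, -1), "non-negative")
})
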