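test_that("radius returns the farthest particle with deterministic ties", {
  single <- point_set(matrix(c(0, 0), 1), model = "EXTERNAL")
  expect_equal(radius(single)$R, 0)

  ps <- point_set(rbind(c(0, 0), c(3, 4)), model = "EXTERNAL")
  expect_equal(radius(ps)$R, 5)
  expect_equal(radius(ps)$index, 2L)

  # two particles at the same radius: the smaller polar angle wins
  tie <- point_set(rbind(c(0, 0), c(0, 2), c(2, 0)), model = "EXTERNAL",
                   reorder = FALSE)
  rad <- radius(tie)
  expect_equal(rad$index, 3L)
  expect_setequal(rad$tied, c(2L, 3L))
})

test_that("radius of gyration matches closed forms", {
  single <- point_set(matrix(c(0, 0), 1), model = "EXTERNAL")
  expect_equal(radius_of_gyration(single), 0)

  pair <- point_set(rbind(c(-0.4, 0), c(0.6, 0)), model = "EXTERNAL",
                    reorder = FALSE)
  expect_equal(radius_of_gyration(pair), 0.5)

  shifted <- point_set(rbind(c(0, 0), c(1, 0)), model = "EXTERNAL")
  expect_equal(radius_of_gyration(shifted), 0.5)          # about centroid
  expect_equal(radius_of_gyration(shifted, about = "origin"),
               sqrt(0.5))
})

test_that("fractal dimension fit recovers planted exponents exactly", {
  n <- seq(10, 20000, by = 37)
  # suppressWarnings: summary.lm flags the residual-free exact fit
  expect_equal(suppressWarnings(
    fractal_dimension(growth_history(n, 0.1 * n)))$D, 1,
    tolerance = 1e-10)
  expect_equal(suppressWarnings(
    fractal_dimension(growth_history(n, 2 * sqrt(n))))$D, 2,
    tolerance = 1e-10)

  expect_error(fractal_dimension(growth_history(1:20, rep(1, 20))),
               "usable samples")
  decay <- growth_history(seq(1100, 5000, by = 100),
                          exp(-seq(1100, 5000, by = 100) / 1000))
  expect_error(fractal_dimension(decay), "beta")
})

test_that("fractal dimension is recovered within 0.05 under noise", {
  for (beta in c(0.5, 0.6, 1.0)) {
    set.seed(101)
    n <- round(seq(1050, 10000, length.out = 400))
    rg <- 0.7 * n^beta * exp(rnorm(length(n), sd = 0.01))
    fit <- fractal_dimension(growth_history(n, rg))
    expect_lt(abs(fit$D - 1 / beta), 0.05)
  }
})

test_that("psi6 separates square, hexagonal and disordered bond order", {
  # cross: each arm bond angle is a multiple of 90 deg, terms cancel
  expect_equal(psi6(generate_vicsek(2)), 0, tolerance = 1e-12)
  expect_equal(psi6(generate_vicsek(4)), 0, tolerance = 1e-12)
  # all bond angles multiples of 60 deg
  expect_equal(psi6(generate_hexagonal(7)), 1, tolerance = 1e-12)
  expect_equal(psi6(generate_hexaflake(3)), 1, tolerance = 1e-12)
  expect_equal(psi6(generate_kagome(120)), 1, tolerance = 1e-12)

  d <- generate_dla(400, seed = 6)$points
  p <- psi6(d)
  expect_gte(p, 0)
  expect_lt(p, 0.2)
  # matches the naive double loop
  g <- build_geometric_graph(d, 1)
  expect_equal(p, brute_psi6(d$coords, g$edges), tolerance = 1e-12)
})

test_that("psi6 is invariant under a global 60-degree rotation", {
  ps <- generate_ba(300, seed = 8)$points
  th <- pi / 3
  rot <- ps$coords %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  ps_rot <- point_set(rot, model = "EXTERNAL", reorder = FALSE)
  expect_equal(psi6(ps_rot), psi6(ps), tolerance = 1e-9)
})

test_that("R >= Rg for every generator output", {
  systems <- list(generate_dla(300, seed = 4)$points,
                  generate_ba(300, seed = 4)$points,
                  generate_vicsek(4), generate_hexaflake(3),
                  generate_hexagonal(200), generate_kagome(200))
  for (ps in systems)
    expect_gte(radius(ps)$R, radius_of_gyration(ps))
})

test_that("spatial_summary assembles the panel consistently", {
  run <- generate_dla(1500, seed = 3)
  ss <- spatial_summary(run$points, history = run$history)
  expect_equal(ss$N, 1500L)
  expect_equal(ss$R, radius(run$points)$R)
  expect_gt(ss$D, 1)
  expect_lt(ss$D, 2.5)
  expect_equal(ss$D, 1 / ss$beta)
})
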