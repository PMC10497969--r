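test_that("the collocation budget reproduces the printed evaluation counts", {
  expect_equal(pce_node_count(5, 4), 254)
  expect_equal(pce_node_count(7, 4), 662)
  expect_equal(pce_node_count(1, 0), 4)
  for (d in 1:4) for (p in 0:3)
    expect_equal(pce_node_count(d, p), 2 * choose(d + p, p) + 2)
})

test_that("surrogates are exact on models inside the basis span", {
  ps <- list(uncertain_parameter("a", 0, 1), uncertain_parameter("b", -2, 5))
  s0 <- build_surrogate(function(x) c(out = 7), ps, order = 2, seed = 1)
  expect_equal(unname(s0$coef[1, 1]), 7, tolerance = 1e-12)
  expect_lt(max(abs(s0$coef[-1, 1])), 1e-10)

  s1 <- build_surrogate(function(x) c(out = 3 + 2 * x[["a"]]), ps,
                        order = 1, seed = 2)
  pts <- cbind(runif(100), runif(100, -2, 5))
  expect_lt(max(abs(predict(s1, pts) - (3 + 2 * pts[, 1]))), 1e-10)

  s2 <- build_surrogate(function(x) c(out = x[["a"]] * x[["b"]]), ps,
                        order = 4, seed = 3)
  expect_lt(max(abs(predict(s2, pts) - pts[, 1] * pts[, 2])), 1e-10)
})

test_that("Sobol indices recover the analytic variance decomposition", {
  ps <- list(uncertain_parameter("a", 0, 1), uncertain_parameter("b", 0, 1))
  s <- build_surrogate(function(x) c(out = x[["a"]]), ps, order = 2, seed = 4)
  sob <- sobol_first_order(s)
  expect_equal(unname(sob["a", 1]), 1, tolerance = 1e-10)
  expect_equal(unname(sob["b", 1]), 0, tolerance = 1e-10)

  # Var = 1/12 + 4/12 -> S = (0.2, 0.8)
  s2 <- build_surrogate(function(x) c(out = x[["a"]] + 2 * x[["b"]]), ps,
                        order = 2, seed = 5)
  sob2 <- sobol_first_order(s2)
  expect_equal(unname(sob2[, 1]), c(0.2, 0.8), tolerance = 1e-10)

  sc <- build_surrogate(function(x) c(out = 1), ps, order = 2, seed = 6)
  expect_equal(unname(sobol_first_order(sc)[, 1]), c(0, 0))
})

test_that("Sobol indices are invariant under affine parameter rescaling", {
  f <- function(x) c(out = sin(x[["a"]]) + 0.3 * x[["b"]]^2)
  ps <- list(uncertain_parameter("a", 0, 1), uncertain_parameter("b", 0, 1))
  s <- build_surrogate(f, ps, order = 4, seed = 7)
  # rescale a -> 10 a - 3 with the model transformed correspondingly
  ps2 <- list(uncertain_parameter("a", -3, 7), uncertain_parameter("b", 0, 1))
  f2 <- function(x) c(out = sin((x[["a"]] + 3) / 10) + 0.3 * x[["b"]]^2)
  s2 <- build_surrogate(f2, ps2, order = 4, seed = 7)
  expect_equal(sobol_first_order(s), sobol_first_order(s2),
               tolerance = 1e-8)
})

test_that("prediction intervals match analytic quantiles of a uniform", {
  ps <- list(uncertain_parameter("x", 0, 1))
  s <- build_surrogate(function(x) c(out = x[["x"]]), ps, order = 1, seed = 8)
  pi_ <- prediction_interval(s, n_samples = 1e4, seed = 9)
  expect_lt(abs(pi_$p5 - 0.05), 0.01)
  expect_lt(abs(pi_$p95 - 0.95), 0.01)
  expect_lte(pi_$p5, pi_$p95)

  sc <- build_surrogate(function(x) c(out = 2), ps, order = 1, seed = 10)
  pic <- prediction_interval(sc, n_samples = 1000, seed = 11)
  expect_equal(unname(pic$p5), 2, tolerance = 1e-10)
  expect_equal(unname(pic$p95), 2, tolerance = 1e-10)
})

test_that("case-1 degenerates correctly and ranks volume above position", {
  # single active parameter: its Sobol index is 1 everywhere
  r <- run_case1(order = 2, seed = 12, n_vox = 32L,
                 frequencies = c(1e4, 1e6),
                 angle_range = c(0, 2e-9),
                 distance_span = c(10, 10 + 1e-6))
  # the voxelised response is a staircase in the collapsed parameters, so a
  # little fitted power leaks off the volume terms; volume still carries
  # essentially all the variance
  expect_true(all(r$table$S_volume > 0.85))
  expect_true(all(r$table$S_x < 0.05 & r$table$S_y < 0.05 &
                    r$table$S_z < 0.05 & r$table$S_angle < 0.05))
  expect_true(all(r$table$p5 <= r$table$p95))
})

test_that("case-2 with collapsed ranges has zero variance", {
  geom <- sphere_geometry(R = 5, L = 20, n = 10)
  r <- run_case2(geom, rel_range = 1e-9, order = 1, seed = 13,
                 frequencies = c(1e5, 1e7), tol = 1e-8)
  expect_lt(max(r$table$variance / pmax(r$table$mean^2, 1e-30)), 1e-10)
  expect_equal(unname(unlist(r$table[, c("p5")])),
               unname(unlist(r$table[, c("p95")])), tolerance = 1e-4)
})
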