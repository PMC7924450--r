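test_that("simulators are pure functions of their seed", {
  for (f in list(function(s) simulate_ar1(n = 300, epsilon = 0.5, seed = s),
                 function(s) simulate_ar100(n = 300, epsilon = 0.5, seed = s),
                 function(s) simulate_ar_lag5(n = 300, seed = s),
                 function(s) simulate_tent(n = 100, epsilon = 0.3,
                                           transient = 100, seed = s),
                 function(s) simulate_mvar3(n = 150, seed = s))) {
    expect_identical(f(12), f(12))
    expect_false(identical(f(12), f(13)))
  }
})

test_that("noise-free uncoupled AR recursions collapse to zero from zero start", {
  sim <- simulate_ar1(n = 50, epsilon = 0, nu = 0, seed = 1)
  expect_equal(sim$X, rep(0, 50))
  expect_equal(sim$Y, rep(0, 50))
  # lag-100 coupling cannot act before sample 101 even when coupled
  sim <- simulate_ar100(n = 150, epsilon = 0.9, nu = 0, seed = 1)
  expect_equal(sim$X, rep(0, 150))
  expect_error(simulate_ar100(n = 100), "exceed")
})

test_that("AR(1) sample autocorrelation reflects the self-coefficient", {
  sim <- simulate_ar1(n = 5000, a = 0.9, b = 0.8, epsilon = 0, nu = 0.03,
                      seed = 2)
  r_x <- cor(sim$X[-1], sim$X[-5000])
  r_y <- cor(sim$Y[-1], sim$Y[-5000])
  expect_equal(r_x, 0.9, tolerance = 0.05)
  expect_equal(r_y, 0.8, tolerance = 0.05)
  expect_true(all(is.finite(sim$X)))
})

test_that("tent map orbits behave as the piecewise-linear map dictates", {
  # uncoupled orbit from 0.4 follows the period-2 cycle 0.8, 0.4, ...
  sim <- simulate_tent(n = 16, epsilon = 0, transient = 0, x0 = 0.3, y0 = 0.4,
                       seed = 3)
  expect_equal(sim$Y, rep(c(0.8, 0.4), 8), tolerance = 1e-6)
  # full coupling synchronizes exactly
  sim <- simulate_tent(n = 200, epsilon = 1, transient = 50, seed = 4)
  expect_identical(sim$X, sim$Y)
  # orbits stay on the unit interval
  for (eps in c(0, 0.25, 0.75)) {
    sim <- simulate_tent(n = 2000, epsilon = eps, seed = 5)
    expect_true(all(sim$X >= 0 & sim$X <= 1))
    expect_true(all(sim$Y >= 0 & sim$Y <= 1))
  }
  expect_error(simulate_tent(n = 10, y0 = 1.2), "\\[0, 1\\]")
})

test_that("common-driver system decouples when the driver weights vanish", {
  sim <- simulate_mvar3(n = 2000, transient = 100, cx = 0, cy = 0, seed = 6)
  expect_lt(abs(cor(sim$X, sim$Y)), 0.15)
  expect_lt(abs(cor(sim$X, sim$Z)), 0.15)
  expect_length(sim$Z, 2000)
})

test_that("non-uniform sampling removes the requested count and keeps order", {
  x <- cumsum(rep(1, 2000))  # strictly increasing so order is observable
  y <- rnorm(2000)
  ns <- nonuniform_sample(x, y, alpha = 50, seed = 7)
  expect_length(ns$x, 1000)
  expect_length(ns$y, 1000)
  expect_true(all(diff(ns$x) > 0))
  expect_equal(ns$y, y[1:1000])
  ident <- nonuniform_sample(x, y, alpha = 0, seed = 8)
  expect_equal(ident$x, x)
  expect_equal(ident$y, y)
  expect_error(nonuniform_sample(x, y, alpha = 100), "alpha")
})

test_that("moving average and decimation do the documented length bookkeeping", {
  expect_equal(moving_average(c(1, 2, 3, 4), window = 3), c(2, 3))
  expect_equal(moving_average(1:10, window = 1), as.numeric(1:10))
  expect_length(moving_average(rnorm(2000), window = 3), 1998)
  expect_error(moving_average(rnorm(2), window = 3), "exceed")
  expect_equal(decimate(c(1, 2, 3, 4), 2), c(1, 3))
  expect_equal(decimate(1:7, 1), 1:7)
  expect_length(moving_average(decimate(rnorm(2000), 2), window = 3), 998)
})
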