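test_that("window decomposition bookkeeping", {
  x <- rnorm(1000)
  wins <- decompose_windows(x, L = 150, w = 15, delta = 80)
  expect_length(wins, 11)
  expect_equal(wins[[1]]$start_index, 150L)
  expect_equal(wins[[1]]$x_past, x[1:150])
  expect_equal(wins[[1]]$dx, x[151:165])
  expect_equal(wins[[2]]$start_index, 230L)
  # boundary: exactly one window when the series is exactly L + w long
  expect_length(decompose_windows(rnorm(165), L = 150, w = 15, delta = 80), 1)
  expect_error(decompose_windows(rnorm(164), L = 150, w = 15, delta = 80),
               "too short")
  expect_error(decompose_windows(rnorm(200), y = rnorm(199), L = 150, w = 15,
                                 delta = 80), "equal length")
})

test_that("dynamical compression-complexity agrees with a direct recomputation", {
  set.seed(21)
  for (i in 1:10) {
    L <- sample(10:40, 1)
    w <- sample(3:10, 1)
    B <- sample(2:4, 1)
    xp <- rnorm(L); yp <- rnorm(L); dx <- rnorm(w)
    bxa <- bin_block(c(xp, dx), B)
    bya <- bin_block(c(yp, dx), B)
    expect_equal(dynamical_cc(dx, xp, B),
                 oracle_etc_steps(bxa) / (L + w - 1) -
                   oracle_etc_steps(bin_block(xp, B)) / (L - 1))
    expect_equal(
      dynamical_cc_joint(dx, xp, yp, B),
      oracle_joint_steps(bxa, bya) / (L + w - 1) -
        oracle_joint_steps(bin_block(xp, B), bin_block(yp, B)) / (L - 1))
    expect_gte(dynamical_cc(dx, xp, B), -1)
    expect_lte(dynamical_cc(dx, xp, B), 1)
  }
})

test_that("joint dynamical complexity collapses to the individual one for identical pasts", {
  set.seed(22)
  xp <- rnorm(30)
  dx <- rnorm(8)
  expect_equal(dynamical_cc_joint(dx, xp, xp, B = 2),
               dynamical_cc(dx, xp, B = 2))
})

test_that("self-causality is exactly zero window by window", {
  set.seed(23)
  x <- rnorm(400)
  fit <- ccc(x, x, L = 100, w = 15, delta = 40, B = 2,
             significance = "surrogate", n_surrogates = 20, seed = 1)
  expect_equal(fit$per_window$ccc, rep(0, fit$n_windows))
  expect_equal(fit$mean_ccc, 0)
  expect_equal(fit$p_value, 1)
  expect_equal(fit$sign_label, "null")
})

test_that("CCC is invariant to a common positive affine rescaling", {
  set.seed(24)
  sim <- simulate_ar1(n = 500, epsilon = 0.6, nu = 0.03)
  base <- ccc(sim$X, sim$Y, L = 100, w = 15, delta = 50, B = 2,
              significance = "none")
  scaled <- ccc(5 * sim$X - 2, 5 * sim$Y - 2, L = 100, w = 15, delta = 50,
                B = 2, significance = "none")
  expect_equal(scaled$per_window, base$per_window)
  # the target's own dynamical complexity is additionally invariant to
  # transforms of the target alone (per-block encoding)
  alone <- ccc(5 * sim$X - 2, sim$Y, L = 100, w = 15, delta = 50, B = 2,
               significance = "none")
  expect_equal(alone$per_window$cc_x, base$per_window$cc_x)
})

test_that("per-window CCC values stay within the normalized-ETC bounds", {
  set.seed(25)
  for (i in 1:5) {
    x <- rnorm(300)
    y <- rnorm(300)
    fit <- ccc(x, y, L = 50, w = 10, delta = 25, B = sample(2:8, 1),
               significance = "none")
    expect_true(all(fit$per_window$ccc >= -2 & fit$per_window$ccc <= 2))
  }
})

test_that("conditional CCC with no conditioning equals the pairwise estimator", {
  set.seed(26)
  sim <- simulate_ar1(n = 400, epsilon = 0.7, nu = 0.03)
  pairwise <- ccc(sim$X, sim$Y, L = 100, w = 15, delta = 40, B = 2,
                  significance = "none")
  conditional <- ccc(sim$X, sim$Y, L = 100, w = 15, delta = 40, B = 2,
                     conditioning = list(), significance = "none")
  expect_equal(conditional$per_window, pairwise$per_window)
})

test_that("conditional CCC is invariant to the order of conditioning series", {
  set.seed(27)
  sim <- simulate_mvar3(n = 250, seed = 3)
  w1 <- rnorm(250)
  a <- ccc(sim$X, sim$Z, L = 100, w = 15, delta = 20, B = 2,
           conditioning = list(sim$Y, w1), significance = "none")
  b <- ccc(sim$X, sim$Z, L = 100, w = 15, delta = 20, B = 2,
           conditioning = list(w1, sim$Y), significance = "none")
  expect_equal(a$per_window$ccc, b$per_window$ccc)
})

test_that("coupled AR(1) yields significant causality in the causal direction", {
  set.seed(28)
  n_sig <- 0
  trials <- 10
  for (i in seq_len(trials)) {
    sim <- simulate_ar1(n = 1000, epsilon = 0.8, nu = 0.03)
    fit <- ccc(sim$X, sim$Y, L = 150, w = 15, delta = 80, B = 2,
               significance = "ttest")
    if (fit$p_value < 0.05 && fit$mean_ccc > 0) n_sig <- n_sig + 1
  }
  expect_gte(n_sig, 0.9 * trials)
  # circular-shift surrogates preserve the source's marginal distribution,
  # which carries part of the signal here, so the surrogate null sits near
  # the observed mean rather than near zero: the test is conservative by
  # construction for this kind of coupling
  sim <- simulate_ar1(n = 1000, epsilon = 0.8, nu = 0.03, seed = 99)
  fit <- ccc(sim$X, sim$Y, L = 150, w = 15, delta = 80, B = 2,
             significance = "surrogate", n_surrogates = 60, seed = 100)
  expect_true(is.finite(fit$p_value))
  expect_gt(fit$mean_ccc, 0.05)
})

test_that("independent Gaussian series give a null causality estimate", {
  set.seed(29)
  trials <- 30
  means_yx <- means_xy <- numeric(trials)
  for (i in seq_len(trials)) {
    x <- rnorm(600)
    y <- rnorm(600)
    means_yx[i] <- ccc(x, y, L = 150, w = 15, delta = 80, B = 2,
                       significance = "none")$mean_ccc
    means_xy[i] <- ccc(y, x, L = 150, w = 15, delta = 80, B = 2,
                       significance = "none")$mean_ccc
  }
  se <- function(v) sd(v) / sqrt(length(v))
  expect_lt(abs(mean(means_yx)), 3 * se(means_yx))
  expect_lt(abs(mean(means_xy)), 3 * se(means_xy))
})

test_that("complexity rate is a distinct quantity from dynamical complexity", {
  xp <- c(1, 5, 2, 8, 3, 7, 1, 6, 2, 9)
  expect_equal(complexity_rate(xp, xp, B = 2), 0)
  expect_equal(complexity_rate(rep(1, 6), rep(2, 6), B = 2), 0)
  expect_error(complexity_rate(rnorm(4), rnorm(6), B = 2), "equal-length")
  # generally CR != DC on the same equal-length blocks
  set.seed(30)
  diffs <- replicate(20, {
    xp <- rnorm(12); dx <- rnorm(12)
    abs(complexity_rate(dx, xp, B = 2) - dynamical_cc(dx, xp, B = 2))
  })
  expect_gt(max(diffs), 1e-6)
})

test_that("ccc rejects malformed input", {
  expect_error(ccc(rnorm(100), rnorm(99), L = 20, w = 5), "equal length")
  expect_error(ccc(c(rnorm(99), NA), rnorm(100), L = 20, w = 5), "missing")
  expect_error(ccc(rnorm(100), rnorm(100), L = 1, w = 5), "'L'")
  expect_error(ccc(rnorm(20), rnorm(20), L = 18, w = 5), "too short")
})

test_that("ccc objects support the standard S3 verbs", {
  sim <- simulate_ar1(n = 400, epsilon = 0.8, nu = 0.03, seed = 55)
  fit <- ccc(sim$X, sim$Y, L = 100, w = 15, delta = 40, B = 2,
             significance = "ttest")
  expect_s3_class(fit, "ccc")
  expect_named(coef(fit), "mean_ccc")
  expect_equal(unname(coef(fit)), fit$mean_ccc)
  expect_identical(as.data.frame(fit), fit$per_window)
  expect_output(print(fit), "mean CCC")
  expect_output(print(summary(fit)), "CC\\(dx\\|x_past\\)")
  pw <- fit$per_window
  expect_equal(pw$ccc, pw$cc_x - pw$cc_xy)
})
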