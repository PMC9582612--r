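test_that("the excitation model obeys its analytic anchor points", {
  p <- safety_params(a = 0.5, b = 1, k2 = 1, k4 = 1, k6 = 1)
  expect_equal(predict_velec(p, 0, 1e-4, 1000), 0)
  # construct b i^k2 t^k4 z^k6 = e^2 - 1 in fitting units -> V = 1
  p2 <- safety_params(a = 0.5, b = exp(2) - 1, k2 = 1, k4 = 1, k6 = 1)
  expect_equal(predict_velec(p2, 1e-6, 1e-6, 1e3), 1.0, tolerance = 1e-12)
  expect_error(predict_velec(p, -1e-6, 1e-4, 1000), "non-negative")
})

test_that("prediction matches an independent evaluation path", {
  set.seed(101)
  for (rep in 1:200) {
    p <- random_safety_params()
    i <- 10^runif(1, -6, -3); t <- 10^runif(1, -5, -3)
    z <- 10^runif(1, 2, 5)
    uc <- p$unit_convention
    # second path: plain log(), explicit scaling, no log1p
    expected <- p$a * log(p$b * (i / uc$i_scale)^p$k2 *
                            (t / uc$t_scale)^p$k4 *
                            (z / uc$z_scale)^p$k6 + 1)
    expect_equal(predict_velec(p, i, t, z), expected, tolerance = 1e-12)
  }
})

test_that("the closed-form inverse is exact against the forward model", {
  p <- safety_params(a = 0.3, b = 0.002, k2 = 1, k4 = 0.9, k6 = 1)
  expect_equal(invert_ilimit(p, 0, 1e-4, 1000), 0)
  set.seed(7)
  for (rep in 1:200) {
    p <- random_safety_params()
    e <- runif(1, 0.1, 1.5); t <- 10^runif(1, -5, -3)
    z <- 10^runif(1, 2, 5)
    i_lim <- invert_ilimit(p, e, t, z)
    expect_equal(predict_velec(p, i_lim, t, z), e, tolerance = 1e-9)
  }
  expect_error(invert_ilimit(p, 0.5, 0, 1000), "positive")
})

test_that("the diameter form is the literal power-law substitution", {
  p <- safety_params(a = 0.3, b = 0.002, k2 = 1, k4 = 0.9, k6 = 1)
  sc <- structure(list(alpha = 6.6e-4, d1 = -1.67, r2 = 1),
                  class = "scaling_params")
  d <- 150e-6
  expect_identical(ilimit_vs_diameter(p, sc, 0.6, 1e-4, d),
                   invert_ilimit(p, 0.6, 1e-4, sc$alpha * d^sc$d1))
  # negative d1: larger contacts take more current
  il <- ilimit_vs_diameter(p, sc, 0.6, 1e-4,
                           c(30, 100, 300, 1000) * 1e-6)
  expect_true(all(diff(il) > 0))
  # closed-form scaling at k2 = k6 = 1: doubling D scales by 2^1.67
  expect_equal(ilimit_vs_diameter(p, sc, 0.6, 1e-4, 2 * d) /
                 ilimit_vs_diameter(p, sc, 0.6, 1e-4, d),
               2^1.67, tolerance = 1e-9)
})

test_that("single-factor fits recover the generating constants", {
  x <- 10^seq(0.5, 2.5, length.out = 12) * 1e-6   # current ladder
  v <- log1p(0.01 * (x / 1e-6)^1.0)
  fit <- fit_single_factor("current", x, v)
  expect_equal(fit$k_scale, 0.01, tolerance = 1e-6)
  expect_equal(fit$k_exp, 1.0, tolerance = 1e-6)
  expect_false(fit$degenerate)
  # all-zero excitations flag the degenerate limit
  z <- fit_single_factor("current", x, rep(0, 12))
  expect_true(z$degenerate)
  expect_equal(z$k_scale, 0)
  expect_error(fit_single_factor("current", x[1:3], v[1:3]), "5 points")
})

test_that("single-factor exponents stay within 0.05 at 1% noise", {
  x <- 10^seq(1, 2, length.out = 20) * 1e-6
  v0 <- log1p(0.01 * (x / 1e-6)^1.0)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    v <- v0 * (1 + rnorm(20, 0, 0.01))
    abs(fit_single_factor("current", x, v)$k_exp - 1.0)
  }, 0)
  expect_lt(max(errs), 0.05)
})

test_that("the full-model fit round-trips noiseless grids exactly", {
  truth <- material_preset("PtNR")$k_true
  g <- generate_excitation_grid(
    truth, c(20, 63, 200, 630, 2000) * 1e-6,
    c(100, 180, 320, 560, 1000) * 1e-6,
    6.6e-4 * (c(100, 200, 400) * 1e-6)^-1.67, rel_sd = 0, seed = 1)
  fit <- fit_full_model(g)
  for (nm in c("a", "b", "k2", "k4", "k6")) {
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-3)
  }
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
})

test_that("a constant factor is rejected by name unless fixed", {
  truth <- material_preset("PtNR")$k_true
  g <- generate_excitation_grid(truth, c(20, 63, 200, 630, 2000) * 1e-6,
                                c(100, 320, 1000) * 1e-6, 1000,
                                rel_sd = 0, seed = 1)
  expect_error(fit_full_model(g), "z_imag")
  fit <- fit_full_model(g, fixed = c(k6 = 1))
  expect_equal(fit$k6, 1)
  expect_equal(fit$a, truth$a, tolerance = 1e-3)
})

test_that("full-model parameters are recovered under 1% noise", {
  truth <- material_preset("PtNR")$k_true
  zv <- 6.6e-4 * (c(100, 200, 400) * 1e-6)^-1.67
  errs <- sapply(1:50, function(s) {
    g <- generate_excitation_grid(truth, c(20, 63, 200, 630, 2000) * 1e-6,
                                  c(100, 180, 320, 560, 1000) * 1e-6,
                                  zv, rel_sd = 0.01, seed = s)
    fit <- fit_full_model(g)
    vapply(c("a", "b", "k2", "k4", "k6"), function(nm)
      abs(fit[[nm]] - truth[[nm]]) / truth[[nm]], 0)
  })
  expect_lt(max(apply(errs, 1, stats::median)), 0.05)
})

test_that("k6 transfer recovers the in-vivo exponent and beats freezing", {
  pre <- material_preset("PtNR")
  truth_b <- pre$k_true
  g_b <- generate_excitation_grid(
    truth_b, c(20, 63, 200, 630, 2000) * 1e-6,
    c(100, 180, 320, 560, 1000) * 1e-6,
    pre$alpha * (200e-6)^pre$d1, rel_sd = 0.01, seed = 21)
  p_bench <- fit_full_model(g_b, fixed = c(k6 = 1))
  truth_i <- safety_params(truth_b$a, truth_b$b, truth_b$k2, truth_b$k4,
                           pre$k6_invivo)
  z_i <- pre$alpha * (c(30, 50, 100, 200) * 1e-6)^pre$d1 *
    pre$invivo_impedance_multiplier
  g_i <- generate_excitation_grid(truth_i, c(20, 200, 2000) * 1e-6,
                                  c(100, 320, 1000) * 1e-6, z_i,
                                  rel_sd = 0.01, seed = 22)
  tr <- holdout_transfer(p_bench, g_i)
  expect_equal(tr$k6_refit, 1.08, tolerance = 0.02 / 1.08)
  # freezing k6 at the benchtop value fits the held-out set worse
  pred_frozen <- predict_velec(p_bench, g_i$i_inj, g_i$t_pw, g_i$z_imag)
  r2_frozen <- 1 - sum((g_i$v_elec - pred_frozen)^2) /
    sum((g_i$v_elec - mean(g_i$v_elec))^2)
  expect_gt(tr$r2, r2_frozen)
})

test_that("a perfect transfer reports unit R2 and p = 1", {
  p <- safety_params(a = 0.3, b = 0.002, k2 = 1, k4 = 0.9, k6 = 1)
  g <- expand.grid(i_inj = c(1, 3, 10) * 1e-5,
                   t_pw = c(1, 3, 10) * 1e-4, z_imag = c(500, 2000))
  g$v_elec <- predict_velec(p, g$i_inj, g$t_pw, g$z_imag)
  tr <- holdout_transfer(p, g)
  expect_equal(tr$r2, 1, tolerance = 1e-9)
  expect_equal(tr$t_test_p, 1)
})

test_that("the Shannon limit solves the log-log boundary exactly", {
  s <- shannon_limit(1e-3, 1e-4, k = 1.8)
  expect_equal(s$area_cm2, pi * 0.05^2, tolerance = 1e-12)
  expect_equal(s$q_per_phase, 0.704, tolerance = 1e-3)
  expect_equal(s$i_limit_a, 7.04e-3, tolerance = 1e-3)
  # the defining identity: Q^2 = A 10^k
  expect_equal(s$q_per_phase^2, s$area_cm2 * 10^1.8, tolerance = 1e-12)
  # charge density times area is the charge per phase
  expect_equal(s$charge_density * s$area_cm2, s$q_per_phase,
               tolerance = 1e-12)
  # doubling t_pw halves the current, leaves the charge unchanged
  s2 <- shannon_limit(1e-3, 2e-4, k = 1.8)
  expect_equal(s2$i_limit_a, s$i_limit_a / 2, tolerance = 1e-12)
  expect_equal(s2$q_per_phase, s$q_per_phase, tolerance = 1e-12)
  expect_error(shannon_limit(-1, 1e-4), "positive")
})

test_that("adjusted R2 matches a brute-force recomputation", {
  expect_equal(adjusted_r2(1:10, 1:10, 3), 1)
  set.seed(3)
  obs <- rnorm(20)
  expect_lte(adjusted_r2(obs, rep(mean(obs), 20), 2), 0)
  for (rep in 1:50) {
    obs <- rnorm(15); pred <- obs + rnorm(15, 0, 0.3)
    n <- 15; k <- 4
    r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    expect_equal(adjusted_r2(obs, pred, k),
                 1 - (1 - r2) * (n - 1) / (n - k - 1), tolerance = 1e-12)
  }
  expect_error(adjusted_r2(1:3, 1:3, 3), "more observations")
})

test_that("excitation and limit are monotone in every factor", {
  set.seed(11)
  for (rep in 1:20) {
    p <- random_safety_params()
    i <- 10^seq(-6, -3, length.out = 7)
    expect_true(all(diff(predict_velec(p, i, 2e-4, 1e3)) > 0))
    t <- 10^seq(-5, -3, length.out = 7)
    expect_true(all(diff(predict_velec(p, 1e-4, t, 1e3)) > 0))
    z <- 10^seq(2, 5, length.out = 7)
    expect_true(all(diff(predict_velec(p, 1e-4, 2e-4, z)) > 0))
    expect_true(all(diff(invert_ilimit(p, 0.6, t, 1e3)) < 0))
    expect_true(all(diff(invert_ilimit(p, 0.6, 2e-4, z)) < 0))
    e <- seq(0.1, 1.5, length.out = 7)
    expect_true(all(diff(invert_ilimit(p, e, 2e-4, 1e3)) > 0))
  }
})
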