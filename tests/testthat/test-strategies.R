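tol <- selfrep_tolerances()

test_that("nutrient-only law equals the closed-form optimum", {
  expect_equal(f_nutrient(1, 0.003), 0.5, tolerance = 1e-15)
  expect_equal(f_nutrient(0, 0.003), 0)
  set.seed(5)
  E <- exp(runif(100, log(0.01), log(50)))
  expect_lt(max(abs(f_nutrient(E, 0.003) -
                    optimal_allocation_env(E, 0.003)$alpha_opt)),
            tol$identity)
})

test_that("Michaelis-Menten approximation tracks the nutrient-only law", {
  expect_equal(f_mm_approx(2, 2), 0.5)
  expect_equal(f_mm_approx(1e9, 2), 1, tolerance = 1e-8)
  expect_error(f_mm_approx(1, K_mE = -1), "positive")
  K_mE <- default_strategy_constants(0.003)$K_mE
  E <- seq(0.01, 10, length.out = 500)
  expect_lt(max(abs(f_mm_approx(E, K_mE) - f_nutrient(E, 0.003))), 0.05)
})

test_that("Hill approximation tracks the optimal steady-state curve", {
  expect_equal(g_hill_approx(0.3, 0.3), 0.5)
  expect_equal(g_hill_approx(0, 0.3), 0)
  expect_error(g_hill_approx(1, K_mp = 0), "positive")
  K_mp <- default_strategy_constants(0.003)$K_mp
  p <- seq(0, 1, length.out = 500)
  expect_lt(max(abs(g_hill_approx(p, K_mp) - optimal_curve_g(p, 0.003))),
            0.05)
})

test_that("on-off law is determined by the side of the optimal curve", {
  params <- nondim_params(1, 0.003)
  opt <- optimal_allocation_env(1, 0.003)
  p <- c(0.02, 0.1, 0.5)
  g <- optimal_curve_g(p, 0.003)
  expect_equal(h_onoff(p, g + 0.01, params), c(0, 0, 0))
  expect_equal(h_onoff(p, g - 0.01, params), c(1, 1, 1))
  expect_equal(h_onoff(opt$p_hat_opt, opt$r_hat_opt, params), 0.5)
})

test_that("smooth surrogate approximates the on-off law away from the curve", {
  params <- nondim_params(1, 0.003)
  p <- seq(0.01, 1, length.out = 60)
  g <- optimal_curve_g(p, 0.003)
  expect_equal(h_smooth(p, g, params), rep(0.5, 60))
  expect_lt(max(h_smooth(p, 2 * g, params)), 1e-20)
  # degenerate corner defined by continuity
  expect_equal(h_smooth(0, 0, params), 0.5)
  # sup-distance to the discontinuous law outside a relative band
  for (side in c(1.06, 0.94)) {
    r <- pmin(side * g, 1)
    keep <- abs(r - g) > 0.05 * g
    d <- abs(h_smooth(p[keep], r[keep], params) -
             h_onoff(p[keep], r[keep], params))
    expect_lt(max(d), 1e-2)
  }
})

test_that("half-saturation fitting recovers exact constants and is grid-stable", {
  k <- fit_half_saturation(function(x) f_mm_approx(x, 1.7), f_mm_approx,
                           domain = c(0.01, 10))
  expect_equal(k, 1.7, tolerance = 1e-6)
  k1 <- fit_half_saturation(function(x) optimal_curve_g(x, 0.003),
                            g_hill_approx, domain = c(0, 1), n_grid = 400)
  k2 <- fit_half_saturation(function(x) optimal_curve_g(x, 0.003),
                            g_hill_approx, domain = c(0, 1), n_grid = 800)
  expect_gt(k1, 0)
  expect_lt(abs(k2 - k1) / k1, 0.01)
})

test_that("strategy specification validates constants", {
  expect_error(strategy("constant"), "alpha")
  expect_error(strategy("constant", list(alpha = 1.4)), "0, 1")
  expect_error(strategy("mm_approx", list(K_mE = -2)), "positive")
  expect_error(strategy("custom"), "function")
  s <- strategy("constant", list(alpha = 0.3))
  expect_equal(strategy_alpha(s, 0.1, 0.2, ref_params()), 0.3)
})

test_that("feedback strategies drive the replicator to the optimal steady state", {
  # static laws (condition C1), convergence to a growing steady state
  # (C2) at the growth-optimal point (C3); the smooth on-off surrogate
  # carries a small equilibrium bias away from E_M = 1 (its sliding mode
  # holds the state slightly off the curve), hence its wider tolerance
  for (E_M in c(0.2, 1, 5)) {
    params <- nondim_params(E_M, 0.003)
    o <- optimal_allocation_env(E_M, 0.003)
    for (kind in c("nutrient_only", "precursor_only", "on_off")) {
      traj <- integrate_closed_loop(strategy(kind),
                                    c(p_hat = 0.3, r_hat = 0.3),
                                    params, horizon = 60, n_report = 500)
      n <- nrow(traj)
      d <- sqrt((traj$p_hat[n] - o$p_hat_opt)^2 +
                (traj$r_hat[n] - o$r_hat_opt)^2)
      expect_lt(d, if (kind == "on_off") 1e-2 else 1e-3)
      expect_gt(traj$mu_hat[n], 0)
      expect_equal(traj$mu_hat[n], o$mu_hat_opt, tolerance = 1e-3)
    }
  }
})
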