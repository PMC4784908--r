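tol <- selfrep_tolerances()

test_that("nondimensionalization maps the reference parameters correctly", {
  nd <- nondimensionalize(dim_params(3.6, 3.6, 1, 0.003))
  expect_equal(nd$params$E_M, 1)
  expect_equal(nd$params$K, 0.003)
  expect_equal(nd$time_scale, 3.6)
  beta <- 0.003
  nd2 <- nondimensionalize(dim_params(2, 2, 1 / beta, beta))
  expect_equal(nd2$params$E_M, 1)
  expect_equal(nd2$params$K, 1)
  expect_error(dim_params(e_M = -1), "positive")
  expect_error(nondim_params(E_M = 0), "positive")
})

test_that("dimensional and nondimensional integrations agree after rescaling", {
  dp <- dim_params(3.6, 3.6, 1, 0.003)
  nd <- nondimensionalize(dp)
  alpha <- 0.35
  y0_dim <- c(p = 0.3 / dp$beta * 0.05, r = 0.3 / dp$beta, log_vol = 0)
  deriv_dim <- function(t, y, p) list(rhs_dim(y, alpha, dp))
  t_hours <- seq(0, 5, length.out = 101)
  sol_dim <- deSolve::ode(y0_dim, t_hours, deriv_dim, NULL,
                          rtol = 1e-12, atol = 1e-14)
  y0_nd <- c(p_hat = dp$beta * y0_dim[["p"]], r_hat = dp$beta * y0_dim[["r"]])
  deriv_nd <- function(t, y, p)
    list(rhs_nondim(c(p_hat = max(y[1], 0), r_hat = min(max(y[2], 0), 1)),
                    alpha, nd$params))
  sol_nd <- deSolve::ode(y0_nd, t_hours * nd$time_scale, deriv_nd, NULL,
                         rtol = 1e-12, atol = 1e-14)
  expect_lt(max(abs(dp$beta * sol_dim[, "p"] - sol_nd[, "p_hat"]) /
                pmax(abs(sol_nd[, "p_hat"]), 1e-8)), 1e-6)
  expect_lt(max(abs(dp$beta * sol_dim[, "r"] - sol_nd[, "r_hat"]) /
                abs(sol_nd[, "r_hat"])), 1e-6)
})

test_that("nondimensional right-hand side has the expected structure", {
  params <- nondim_params(4.76 / 2.23, 0.003)
  ss <- steady_state_for_alpha(0.45, params)
  res <- rhs_nondim(c(p_hat = ss$p_hat, r_hat = ss$r_hat), 0.45, params)
  expect_lt(max(abs(res)), tol$fixed_point)
  # no precursors: no growth, precursor influx only
  res0 <- rhs_nondim(c(p_hat = 0, r_hat = 0.4), 0.7, params)
  expect_equal(res0[["dp_hat"]], (1 - 0.4) * params$E_M)
  expect_equal(res0[["dr_hat"]], 0)
  # all mass in machinery, full allocation: precursors only consumed
  res1 <- rhs_nondim(c(p_hat = 0.5, r_hat = 1), 1, params)
  expect_lt(res1[["dp_hat"]], 0)
  expect_equal(res1[["dr_hat"]], 0)
  expect_error(rhs_nondim(c(p_hat = 0.1, r_hat = 0.5), 1.2, params),
               "alpha")
})

test_that("dimensional right-hand side matches its kinetic definitions", {
  dp <- dim_params(3.6, 3.6, 1, 0.003)
  # r at the density bound: no precursor synthesis
  res <- rhs_dim(c(p = 0.5, r = 1 / dp$beta, log_vol = 0), 0.5, dp)
  v_R <- dp$k_R * (1 / dp$beta) * 0.5 / (dp$K_R + 0.5)
  expect_equal(res[["dp"]], -v_R * (1 + dp$beta * 0.5))
  # half-saturation of macromolecule synthesis
  res2 <- rhs_dim(c(p = dp$K_R, r = 100, log_vol = 0), 0.5, dp)
  expect_equal(res2[["dlog_vol"]], dp$beta * dp$k_R * 100 / 2)
  # consistency with the nondimensional field at random matched states
  set.seed(42)
  for (i in 1:20) {
    p <- runif(1, 0, 200); r <- runif(1, 0, 1 / dp$beta); a <- runif(1)
    f_dim <- rhs_dim(c(p = p, r = r, log_vol = 0), a, dp)
    f_nd <- rhs_nondim(c(p_hat = dp$beta * p, r_hat = dp$beta * r), a,
                       nondimensionalize(dp)$params)
    # d p_hat / d t_hat = beta/k_R * dp/dt
    expect_lt(abs(dp$beta / dp$k_R * f_dim[["dp"]] - f_nd[["dp_hat"]]) /
              max(abs(f_nd[["dp_hat"]]), 1e-10), tol$identity)
    expect_lt(abs(dp$beta / dp$k_R * f_dim[["dr"]] - f_nd[["dr_hat"]]) /
              max(abs(f_nd[["dr_hat"]]), 1e-10), tol$identity)
  }
})

test_that("growth rate saturates in precursors and is linear in machinery", {
  params <- nondim_params(1, 0.003)
  expect_equal(growth_rate_nondim(params$K, 0.8, params), 0.4)
  expect_equal(growth_rate_nondim(0, 0.8, params), 0)
  expect_equal(growth_rate_nondim(1e9, 0.8, params), 0.8, tolerance = 1e-8)
})

test_that("constant-allocation steady state solves the fixed-point equations", {
  params <- nondim_params(0.2, 0.003)
  ss <- steady_state_for_alpha(0.17974, params)
  expect_equal(ss$r_hat, 0.17974)
  expect_equal(ss$p_hat, 0.0245, tolerance = 2e-3)
  res <- rhs_nondim(c(p_hat = ss$p_hat, r_hat = ss$r_hat), ss$alpha, params)
  expect_lt(max(abs(res)), tol$fixed_point)
  # the "+" branch is the only nonnegative root of the quadratic
  b <- (1 - 0.17974) * 0.2 - 0.17974
  minus_root <- (b - sqrt(b^2 + 4 * 0.17974 * (1 - 0.17974) * 0.2 * 0.003)) /
    (2 * 0.17974)
  expect_lt(minus_root, 0)
})

test_that("nontrivial steady states are stable across random environments", {
  set.seed(7)
  for (i in 1:100) {
    alpha <- runif(1, 0.02, 0.98)
    E_M <- exp(runif(1, log(0.05), log(20)))
    ss <- steady_state_for_alpha(alpha, nondim_params(E_M, 0.003))
    expect_true(ss$stable)
    expect_true(all(Re(ss$eigenvalues) < 0))
  }
})

test_that("the trivial fixed point is non-growing and unstable", {
  for (E_M in c(0.2, 1, 5)) {
    ss <- trivial_steady_state(nondim_params(E_M, 0.003))
    expect_equal(c(ss$p_hat, ss$r_hat), c(0, 1))
    expect_equal(ss$mu_hat, 0)
    res <- rhs_nondim(c(p_hat = 0, r_hat = 1), 1, nondim_params(E_M, 0.003))
    expect_lt(max(abs(res)), 1e-12)
    expect_false(ss$stable)
    expect_true(any(Re(ss$eigenvalues) > 0))
  }
})

test_that("boundary allocations return flagged degenerate fixed points", {
  params <- nondim_params(1, 0.003)
  expect_warning(s0 <- steady_state_for_alpha(0, params), "degenerate")
  expect_true(s0$degenerate)
  expect_equal(s0$mu_hat, 0)
  expect_warning(s1 <- steady_state_for_alpha(1, params), "degenerate")
  expect_true(s1$degenerate)
  expect_equal(c(s1$p_hat, s1$r_hat), c(0, 1))
})

test_that("closed-form optimal allocation maximizes steady-state growth", {
  o <- optimal_allocation_env(1, 0.003)
  expect_equal(o$alpha_opt, 0.5, tolerance = 1e-15)
  o2 <- optimal_allocation_env(0.2, 0.003)
  expect_lt(abs(o2$p_hat_opt - 0.024), 5e-4)
  expect_lt(abs(o2$r_hat_opt - 0.18), 5e-3)
  # brute-force grid oracle: maximize the fixed-point growth rate over a
  # dense allocation grid and compare with the closed form
  set.seed(11)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 1e4)
  mu_star <- function(a, E_M, K) {
    b <- (1 - a) * E_M - a
    p <- (b + sqrt(b^2 + 4 * a * (1 - a) * E_M * K)) / (2 * a)
    a * p / (K + p)
  }
  for (i in 1:20) {
    E_M <- exp(runif(1, log(0.05), log(20)))
    K <- exp(runif(1, log(5e-4), log(0.05)))
    a_star <- grid[which.max(mu_star(grid, E_M, K))]
    expect_lt(abs(optimal_allocation_env(E_M, K)$alpha_opt - a_star),
              diff(grid[1:2]) * 1.5)
  }
  # first-order condition: at fixed environment, the steady-state growth
  # rate along the precursor nullcline is stationary at the optimum
  mu_of_p <- function(p, E, K) E * p / (E * (K + p) + (1 + p) * p)
  h <- 1e-7
  dmu <- (mu_of_p(o$p_hat_opt + h, 1, 0.003) -
          mu_of_p(o$p_hat_opt - h, 1, 0.003)) / (2 * h)
  expect_lt(abs(dmu), 1e-6)
})

test_that("dimensional optimum equals the nondimensional route", {
  od <- optimal_allocation_dim(3.6, 3.6, 0.003)
  expect_equal(od$alpha_opt, 0.5, tolerance = 1e-15)
  set.seed(3)
  for (i in 1:20) {
    e_M <- runif(1, 0.1, 10); k_R <- runif(1, 0.5, 10)
    on <- optimal_allocation_env(e_M / k_R, 0.003)
    od <- optimal_allocation_dim(e_M, k_R, 0.003)
    expect_lt(abs(od$alpha_opt - on$alpha_opt), tol$identity)
    expect_lt(abs(od$mu_opt - k_R * on$mu_hat_opt), tol$identity)
  }
  # very fast gene expression needs almost no machinery allocation
  expect_lt(optimal_allocation_dim(1, 1e8, 0.003)$alpha_opt, 1e-3)
})

test_that("optimal steady-state curve is consistent with the environment form", {
  K <- 0.003
  expect_equal(optimal_curve_g(0.0245, K), 0.18, tolerance = 0.005)
  expect_equal(optimal_curve_g(0, K), 0)
  expect_equal(optimal_curve_g(1e9, K), 1, tolerance = 1e-8)
  E_M <- exp(seq(log(0.01), log(100), length.out = 50))
  o <- optimal_allocation_env(E_M, K)
  expect_lt(max(abs(optimal_curve_g(o$p_hat_opt, K) - o$alpha_opt)), 1e-10)
  expect_lt(max(abs(optimal_curve_mu(o$p_hat_opt, K) - o$mu_hat_opt)), 1e-10)
  p <- seq(0, 5, length.out = 500)
  expect_true(all(diff(optimal_curve_g(p, K)) > 0))
})

test_that("trajectories stay in the invariant region under arbitrary allocation", {
  params <- nondim_params(2, 0.003)
  set.seed(99)
  for (i in 1:5) {
    breaks <- seq(0, 10, by = 2)
    alphas <- runif(5)
    sched <- stats::stepfun(breaks[-1], c(alphas, alphas[5]))
    deriv <- function(t, y, p) {
      st <- c(p_hat = max(y[1], 0), r_hat = min(max(y[2], 0), 1))
      list(rhs_nondim(st, sched(t), params))
    }
    y0 <- c(p_hat = runif(1, 0, 1), r_hat = runif(1, 0.05, 0.95))
    sol <- deSolve::ode(y0, seq(0, 10, length.out = 201), deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
    expect_true(all(sol[, "p_hat"] >= -1e-9))
    expect_true(all(sol[, "r_hat"] >= -1e-9 & sol[, "r_hat"] <= 1 + 1e-9))
    mu <- growth_rate_nondim(sol[, "p_hat"], sol[, "r_hat"], params)
    expect_true(all(mu >= -1e-12 & mu <= sol[, "r_hat"] + 1e-9))
  }
})
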