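test_that("transcription constraints are satisfied by simulated trajectories", {
  params <- ref_params()
  prob <- ocp_problem(params, pre_shift_state(), horizon = 10, N = 1000,
                      terminal = "free")
  tr <- transcribe(prob)
  # a constant-allocation trajectory from the stiff integrator is a
  # feasible point of the discrete dynamics up to local truncation error
  alpha <- 0.45
  deriv <- function(t, y, p) {
    st <- c(p_hat = max(y[1], 0), r_hat = min(max(y[2], 0), 1))
    mu <- growth_rate_nondim(st[1], st[2], params)
    list(c(rhs_nondim(st, alpha, params), mu))
  }
  sol <- deSolve::ode(c(prob$init, log_vol = 0), tr$times, deriv, NULL,
                      rtol = 1e-12, atol = 1e-14)
  states <- unname(sol[, 2:4])
  u <- rep(alpha, prob$N)
  expect_lt(max(abs(tr$defects(states, u))), 1e-8)
  # reduced objective agrees with the integrator's log-volume
  expect_equal(tr$objective(u), unname(sol[nrow(sol), 4]),
               tolerance = 1e-6)
  # control bounds are hard
  expect_true(all(tr$lower == 0) && all(tr$upper == 1))
})

test_that("discrete-adjoint gradient matches finite differences", {
  prob <- ocp_problem(ref_params(), pre_shift_state(), horizon = 10,
                      N = 300, terminal = "free")
  tr <- transcribe(prob)
  u0 <- rep(0.4, 300)
  g <- tr$gradient(u0)
  for (i in c(1, 100, 299)) {
    u1 <- u0; u1[i] <- u1[i] + 1e-6
    u2 <- u0; u2[i] <- u2[i] - 1e-6
    fd <- (tr$objective(u1) - tr$objective(u2)) / 2e-6
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("starting at the optimal steady state yields a pure singular solution", {
  o <- optimal_allocation_env(1, 0.003)
  prob <- ocp_problem(ref_params(),
                      c(p_hat = o$p_hat_opt, r_hat = o$r_hat_opt),
                      horizon = 30, N = 500)
  sol <- solve_ocp(prob, init_guess = "constant")
  expect_lt(max(abs(sol$controls - o$alpha_opt)), 1e-3)
  expect_equal(sol$objective, o$mu_hat_opt * 30, tolerance = 1e-4)
  arcs <- classify_arcs(sol)
  expect_equal(arcs$arcs, "singular")
  expect_equal(arcs$n_alternations, 0L)
})

test_that("the upshift solution is bang-bang entering a singular arc", {
  sol <- cached_upshift_ocp(N = 1000)
  arcs <- classify_arcs(sol)
  expect_equal(arcs$arcs[1], "bang1")
  expect_equal(arcs$arcs[length(arcs$arcs)], "singular")
  expect_gte(arcs$n_alternations, 1L)
  expect_equal(arcs$singular_alpha, 0.5, tolerance = 1e-2)
  expect_lt(sol$terminal_violation, 1e-3)
  # halving the bang band moves switch times by at most 2 node spacings
  a2 <- classify_arcs(sol, eps_b = 0.025)
  shared <- seq_len(min(length(arcs$switch_times), length(a2$switch_times)))
  expect_lt(max(abs(arcs$switch_times[shared] - a2$switch_times[shared])),
            2 * 30 / 1000 + 1e-12)
})

test_that("the optimal objective dominates every feedback strategy", {
  sol <- cached_upshift_ocp(N = 1000)
  for (kind in c("nutrient_only", "precursor_only", "on_off")) {
    J_s <- tail(cached_upshift_traj(kind)$log_vol, 1)
    expect_gte(sol$objective, J_s - 1e-6)
  }
})

test_that("objective is stable under grid refinement", {
  J1 <- cached_upshift_ocp(N = 600)$objective
  J2 <- cached_upshift_ocp(N = 1200)$objective
  expect_lt(abs(J2 - J1) / abs(J1), 1e-5)
})

test_that("switching-curve estimate passes through the optimal steady state", {
  params <- ref_params()
  opt <- optimal_allocation_env(1, 0.003)
  inits <- list(
    pre_shift_state(),
    c(p_hat = 0.01, r_hat = 0.1), c(p_hat = 0.01, r_hat = 0.35),
    c(p_hat = 0.15, r_hat = 0.2), c(p_hat = 0.3, r_hat = 0.3),
    c(p_hat = 0.1, r_hat = 0.7))
  swc <- estimate_switching_curve(params, inits, N = 600)
  expect_gte(nrow(swc$samples), 3)
  d <- sqrt((swc$samples$p_hat - opt$p_hat_opt)^2 +
            (swc$samples$r_hat - opt$r_hat_opt)^2)
  expect_lt(min(d), 1e-3)
  # monotone trend in the precursor coordinate (samples carry solver
  # scatter, so rank correlation rather than strict monotonicity)
  expect_gt(cor(swc$samples$p_hat, swc$samples$r_hat, method = "spearman"),
            0.9)
  # the first bang of each solution matches the side of the curve the
  # initial state lies on (above: switch expression off; below: on)
  phi <- stats::approxfun(swc$samples$p_hat, swc$samples$r_hat, rule = 2)
  for (i in seq_along(inits)) {
    u1 <- swc$solutions[[i]]$controls[1]
    above <- inits[[i]][["r_hat"]] > phi(inits[[i]][["p_hat"]])
    if (abs(inits[[i]][["r_hat"]] - phi(inits[[i]][["p_hat"]])) > 0.02)
      expect_equal(u1 > 0.5, !above)
  }
  # closing the loop on the estimated curve recovers the optimal payoff
  fb <- strategy("custom", list(fn = function(p, r, params) {
    target <- pmax(phi(p), 1e-12)
    stats::plogis(100 * (log(target) - log(pmax(r, 1e-12))))
  }))
  traj <- run_upshift(ref_scenario(), fb)
  J_fb <- tail(traj$log_vol, 1)
  J_opt <- cached_upshift_ocp(N = 1000)$objective
  expect_lt((J_opt - J_fb) / J_opt, 0.01)
  expect_error(estimate_switching_curve(params, inits[1:3]), "at least 5")
})
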