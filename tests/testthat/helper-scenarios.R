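# Shared fixtures: reference parameterization, upshift scenario and a
# memoized optimal-control solve (reused across files to keep the suite
# fast).

ref_params <- function() nondim_params(1, 0.003)

ref_scenario <- function(horizon = 30)
  upshift_scenario(pre_factor = 0.2, E_M_post = 1, K = 0.003,
                   horizon = horizon)

pre_shift_state <- function(E_M = 1, pre_factor = 0.2, K = 0.003) {
  o <- optimal_allocation_env(pre_factor * E_M, K)
  c(p_hat = o$p_hat_opt, r_hat = o$r_hat_opt)
}

.ocp_cache <- new.env(parent = emptyenv())

cached_upshift_ocp <- function(N = 1000, E_M = 1, horizon = 30) {
  key <- sprintf("N%d_E%g_H%g", N, E_M, horizon)
  if (is.null(.ocp_cache[[key]])) {
    prob <- ocp_problem(nondim_params(E_M, 0.003),
                        pre_shift_state(E_M), horizon = horizon, N = N)
    .ocp_cache[[key]] <- solve_ocp(prob)
  }
  .ocp_cache[[key]]
}

.traj_cache <- new.env(parent = emptyenv())

cached_upshift_traj <- function(kind, horizon = 30) {
  key <- sprintf("%s_H%g", kind, horizon)
  if (is.null(.traj_cache[[key]]))
    .traj_cache[[key]] <- run_upshift(ref_scenario(horizon), strategy(kind))
  .traj_cache[[key]]
}
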