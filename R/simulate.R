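#' Construct a trajectory object
#'
#' Time-indexed record of a closed-loop (or open-loop) run: state,
#' applied allocation, growth rate, and accumulated log-volume
#' `log_vol(t) = log(Vol(t)/Vol(0))`, which is the integral of the
#' growth rate.
#'
#' @param times increasing dimensionless times.
#' @param p_hat,r_hat,alpha,mu_hat,log_vol columns of equal length.
#' @return Object of classes `replicator_trajectory` and `data.frame`
#'   with columns `t_hat`, `p_hat`, `r_hat`, `alpha`, `mu_hat`,
#'   `log_vol`.
#' @export
replicator_trajectory <- function(times, p_hat, r_hat, alpha, mu_hat,
                                  log_vol) {
  n <- length(times)
  stopifnot(length(p_hat) == n, length(r_hat) == n, length(alpha) == n,
            length(mu_hat) == n, length(log_vol) == n)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    data.frame(t_hat = times, p_hat = p_hat, r_hat = r_hat,
               alpha = alpha, mu_hat = mu_hat, log_vol = log_vol),
    class = c("replicator_trajectory", "data.frame"))
}

#' Integrate the self-replicator under a feedback strategy
#'
#' Stiff integration of the nondimensional model closed by a static
#' allocation strategy, together with the log-volume quadrature
#' `d log_vol/dt_hat = mu_hat`. The discontinuous on-off law is replaced
#' by its smooth surrogate ([h_smooth()]) during integration; the high
#' Hill exponent makes the system stiff, so an implicit BDF method
#' (`deSolve::ode`, `method = "lsoda"` switching to BDF as needed, or
#' `"radau"`) at tight tolerances is used.
#'
#' @param spec a [strategy()] object.
#' @param init initial state: numeric vector or list with `p_hat`,
#'   `r_hat` (and optionally `log_vol`, default 0).
#' @param params a [nondim_params()] object.
#' @param horizon final dimensionless time (default 30).
#' @param n_report number of evenly spaced reporting times (default
#'   2000).
#' @param rtol,atol integrator tolerances.
#' @param method deSolve method (default `"lsoda"`).
#' @return A [replicator_trajectory()].
#' @export
integrate_closed_loop <- function(spec, init, params, horizon = 30,
                                  n_report = 2000,
                                  rtol = selfrep_tolerances()$rtol,
                                  atol = selfrep_tolerances()$atol,
                                  method = "lsoda") {
  params <- as_nondim(params)
  y0 <- c(p_hat = init[["p_hat"]], r_hat = init[["r_hat"]],
          log_vol = if ("log_vol" %in% names(init)) init[["log_vol"]] else 0)
  times <- seq(0, horizon, length.out = n_report)
  deriv <- function(t, y, parms) {
    p <- max(y[1], 0); r <- min(max(y[2], 0), 1)
    a <- strategy_alpha(spec, p, r, params, smooth_onoff = TRUE)
    mu <- r * p / (params$K + p)
    list(c((1 - r) * params$E_M - (1 + p) * mu, mu * (a - r), mu))
  }
  sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = method,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("integration failed at t_hat = %.4g", max(sol[, "time"])))
  p <- sol[, "p_hat"]; r <- sol[, "r_hat"]
  replicator_trajectory(
    times = sol[, "time"], p_hat = p, r_hat = r,
    alpha = strategy_alpha(spec, p, r, params, smooth_onoff = TRUE),
    mu_hat = r * p / (params$K + p),
    log_vol = sol[, "log_vol"])
}

#' Define a nutrient-upshift scenario
#'
#' A step change of the environment at `t_hat = 0`: the replicator sits
#' at the growth-optimal steady state of the pre-shift environment
#' `pre_factor * E_M_post` and is then integrated under `E_M_post`.
#'
#' @param pre_factor multiplier defining the pre-shift environment
#'   (default 0.2; values below 1 give an upshift).
#' @param E_M_post post-shift environment input (default 1).
#' @param K dimensionless half-saturation (default 0.003).
#' @param horizon integration horizon (default 30).
#' @param n_report reporting grid size (default 2000).
#' @param rtol,atol integrator tolerances.
#' @return Object of class `upshift_scenario`.
#' @export
upshift_scenario <- function(pre_factor = 0.2, E_M_post = 1, K = 0.003,
                             horizon = 30, n_report = 2000,
                             rtol = selfrep_tolerances()$rtol,
                             atol = selfrep_tolerances()$atol) {
  if (pre_factor <= 0) stop("pre_factor must be positive")
  if (horizon <= 0) stop("horizon must be positive")
  structure(list(pre_factor = pre_factor, E_M_post = E_M_post, K = K,
                 horizon = horizon, n_report = n_report,
                 rtol = rtol, atol = atol),
            class = "upshift_scenario")
}

#' Simulate a nutrient upshift under a feedback strategy
#'
#' Initializes at the growth-optimal steady state of the pre-shift
#' environment and integrates the closed loop in the post-shift
#' environment.
#'
#' @param scenario an [upshift_scenario()].
#' @param spec a [strategy()] object.
#' @return A [replicator_trajectory()].
#' @export
run_upshift <- function(scenario, spec) {
  stopifnot(inherits(scenario, "upshift_scenario"))
  pre <- optimal_allocation_env(scenario$pre_factor * scenario$E_M_post,
                                scenario$K)
  integrate_closed_loop(
    spec, init = c(p_hat = pre$p_hat_opt, r_hat = pre$r_hat_opt),
    params = nondim_params(scenario$E_M_post, scenario$K),
    horizon = scenario$horizon, n_report = scenario$n_report,
    rtol = scenario$rtol, atol = scenario$atol)
}

#' Biomass ratio between two trajectories
#'
#' `Vol/Vol_ref = exp(log_vol - log_vol_ref)` on the trajectory's time
#' grid; the reference's log-volume is resampled by monotone cubic
#' (Hyman) interpolation when the grids differ. Interpolation happens in
#' log space, where the accumulated volume is smooth.
#'
#' @param traj a [replicator_trajectory()].
#' @param reference the reference trajectory (e.g. the optimal-control
#'   solution's trajectory); its horizon must cover the trajectory's.
#' @return List with `t_hat`, `ratio` (time series) and `final` (the
#'   ratio at the final time).
#' @export
biomass_ratio <- function(traj, reference) {
  tt <- traj$t_hat
  if (max(reference$t_hat) < max(tt) - 1e-9)
    stop("reference horizon shorter than trajectory horizon")
  lv_ref_fun <- stats::splinefun(reference$t_hat, reference$log_vol,
                                 method = "hyman")
  ratio <- exp(traj$log_vol - lv_ref_fun(tt))
  list(t_hat = tt, ratio = ratio, final = ratio[length(ratio)])
}
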