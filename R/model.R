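#' Growth rate of the nondimensional self-replicator
#'
#' `mu_hat = r_hat * p_hat / (K + p_hat)`: the macromolecule synthesis
#' rate per unit volume, which equals the relative rate of volume increase.
#' Vectorized over `p_hat` and `r_hat`.
#'
#' @param p_hat dimensionless precursor concentration (>= 0).
#' @param r_hat dimensionless gene-expression-machinery concentration,
#'   in \[0, 1\].
#' @param params a [nondim_params()] object (or coercible).
#' @return Dimensionless growth rate(s) in \[0, 1\].
#' @export
growth_rate_nondim <- function(p_hat, r_hat, params) {
  params <- as_nondim(params)
  r_hat * p_hat / (params$K + p_hat)
}

#' Right-hand side of the nondimensional self-replicator ODEs
#'
#' The two-variable rescaled model:
#' `dp_hat/dt_hat = (1 - r_hat) * E_M - (1 + p_hat) * mu_hat`,
#' `dr_hat/dt_hat = mu_hat * (alpha - r_hat)`, with
#' `mu_hat = r_hat * p_hat / (K + p_hat)`.
#'
#' @param state numeric vector or list with `p_hat` and `r_hat`.
#' @param alpha resource allocation parameter in \[0, 1\]: fraction of the
#'   macromolecule synthesis flux directed to the gene-expression
#'   machinery.
#' @param params a [nondim_params()] object.
#' @return Numeric vector `c(dp_hat, dr_hat)`.
#' @export
rhs_nondim <- function(state, alpha, params) {
  params <- as_nondim(params)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  p <- state[["p_hat"]]; r <- state[["r_hat"]]
  if (p < 0) stop("p_hat must be nonnegative")
  if (r < 0 || r > 1) stop("r_hat must lie in [0, 1]")
  mu <- r * p / (params$K + p)
  c(dp_hat = (1 - r) * params$E_M - (1 + p) * mu,
    dr_hat = mu * (alpha - r))
}

#' Right-hand side of the dimensional self-replicator ODEs
#'
#' `dp/dt = v_M - v_R * (1 + beta * p)`, `dr/dt = v_R * (alpha - beta * r)`,
#' `d(log Vol)/dt = mu = beta * v_R`, with precursor synthesis
#' `v_M = e_M * (1/beta - r)` and macromolecule synthesis
#' `v_R = k_R * r * p / (K_R + p)`.
#'
#' @param state numeric vector or list with `p` \[g/L\], `r` \[g/L\] and
#'   `log_vol` (natural log of volume relative to the initial volume).
#' @param alpha allocation parameter in \[0, 1\].
#' @param params a [dim_params()] object.
#' @return Numeric vector `c(dp, dr, dlog_vol)`.
#' @export
rhs_dim <- function(state, alpha, params) {
  stopifnot(inherits(params, "dim_params"))
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  p <- state[["p"]]; r <- state[["r"]]
  if (p < 0) stop("p must be nonnegative")
  if (r < 0 || r > 1 / params$beta) stop("r must lie in [0, 1/beta]")
  v_M <- params$e_M * (1 / params$beta - r)
  v_R <- params$k_R * r * p / (params$K_R + p)
  mu <- params$beta * v_R
  c(dp = v_M - v_R * (1 + params$beta * p),
    dr = v_R * (alpha - params$beta * r),
    dlog_vol = mu)
}

## Numeric Jacobian of the nondimensional RHS at a state, central
## differences with relative step (internal).
jacobian_nondim <- function(p_hat, r_hat, alpha, params, rel_step = 1e-7) {
  f <- function(p, r) {
    mu <- r * p / (params$K + p)
    c((1 - r) * params$E_M - (1 + p) * mu, mu * (alpha - r))
  }
  hp <- rel_step * max(abs(p_hat), 1)
  hr <- rel_step * max(abs(r_hat), 1)
  J <- cbind((f(p_hat + hp, r_hat) - f(p_hat - hp, r_hat)) / (2 * hp),
             (f(p_hat, r_hat + hr) - f(p_hat, r_hat - hr)) / (2 * hr))
  dimnames(J) <- list(c("dp_hat", "dr_hat"), c("p_hat", "r_hat"))
  J
}

new_steady_state <- function(p_hat, r_hat, alpha, params,
                             degenerate = FALSE) {
  mu <- growth_rate_nondim(p_hat, r_hat, params)
  J <- jacobian_nondim(p_hat, r_hat, alpha, params)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(
    p_hat = p_hat, r_hat = r_hat, mu_hat = mu, alpha = alpha,
    stable = all(Re(ev) < 0), eigenvalues = ev,
    degenerate = degenerate, params = params
  ), class = "replicator_steady_state")
}

#' @export
print.replicator_steady_state <- function(x, ...) {
  cat(sprintf(
    "Steady state: p_hat = %.6g, r_hat = %.6g, mu_hat = %.6g (alpha = %.6g, %s)\n",
    x$p_hat, x$r_hat, x$mu_hat, x$alpha,
    if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Nontrivial steady state for a constant allocation
#'
#' For constant `alpha` in (0, 1) and constant environment the system has a
#' nontrivial steady state with `r_hat* = alpha` and `p_hat*` the
#' nonnegative root of a quadratic:
#' `p_hat* = (b + sqrt(b^2 + 4 alpha (1 - alpha) E_M K)) / (2 alpha)` with
#' `b = (1 - alpha) E_M - alpha`. The "+" branch is the only nonnegative
#' root. Stability is assessed from the numerically differentiated
#' Jacobian.
#'
#' At the boundary allocations the fixed point degenerates: `alpha = 0`
#' gives the non-growing state `r_hat* = 0` and `alpha = 1` the state
#' `(0, 1)`; both are returned with a warning and `degenerate = TRUE`.
#'
#' @param alpha constant allocation in (0, 1).
#' @param params a [nondim_params()] object.
#' @return A `replicator_steady_state` with fields `p_hat`, `r_hat`,
#'   `mu_hat`, `alpha`, `stable`, `eigenvalues`, `degenerate`.
#' @export
steady_state_for_alpha <- function(alpha, params) {
  params <- as_nondim(params)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (alpha == 0) {
    ## Eq-21 limit: r_hat* -> 0 while p_hat* = E_M/alpha diverges; no
    ## finite growing fixed point exists.
    warning("alpha = 0 is degenerate: non-growing limit, p_hat unbounded")
    return(structure(list(
      p_hat = Inf, r_hat = 0, mu_hat = 0, alpha = 0,
      stable = NA, eigenvalues = NULL, degenerate = TRUE, params = params
    ), class = "replicator_steady_state"))
  }
  if (alpha == 1) {
    warning("alpha = 1 is degenerate: coincides with the trivial fixed point")
    return(new_steady_state(p_hat = 0, r_hat = 1, alpha = 1, params,
                            degenerate = TRUE))
  }
  E <- params$E_M; K <- params$K
  b <- (1 - alpha) * E - alpha
  p_star <- (b + sqrt(b^2 + 4 * alpha * (1 - alpha) * E * K)) / (2 * alpha)
  new_steady_state(p_hat = p_star, r_hat = alpha, alpha = alpha, params)
}

#' Trivial (non-growing) steady state
#'
#' The state `(p_hat, r_hat) = (0, 1)`: all mass in gene-expression
#' machinery, no precursors, zero growth. It is a fixed point for every
#' allocation (growth is zero, so nothing is diluted or synthesized) and
#' is unstable: for any interior allocation the linearization is a
#' saddle. At `alpha = 1` exactly, the unstable eigenvalue degenerates
#' to zero, so the Jacobian is evaluated at an interior allocation by
#' default.
#'
#' @inheritParams steady_state_for_alpha
#' @param alpha allocation at which to evaluate the Jacobian (default
#'   0.5).
#' @return A `replicator_steady_state`.
#' @export
trivial_steady_state <- function(params, alpha = 0.5) {
  params <- as_nondim(params)
  new_steady_state(p_hat = 0, r_hat = 1, alpha = alpha, params)
}

#' Growth-optimal steady-state allocation for an environment
#'
#' Closed-form maximizer of the steady-state growth rate over the constant
#' allocation:
#' `alpha_opt* = (E_M + sqrt(K E_M)) / (E_M + 2 sqrt(K E_M) + 1)` and
#' `mu_hat_opt* = E_M / (E_M + 2 sqrt(K E_M) + 1)`.
#'
#' @param E_M dimensionless environment input (> 0). Vectorized.
#' @param K dimensionless half-saturation constant (> 0).
#' @return List with `alpha_opt`, `mu_hat_opt`, `p_hat_opt`, `r_hat_opt`
#'   (each vectorized along `E_M`).
#' @examples
#' optimal_allocation_env(1, 0.003)$alpha_opt  # exactly 0.5
#' @export
optimal_allocation_env <- function(E_M, K) {
  if (any(E_M <= 0) || K <= 0) stop("E_M and K must be strictly positive")
  s <- sqrt(K * E_M)
  den <- E_M + 2 * s + 1
  alpha_opt <- (E_M + s) / den
  mu_opt <- E_M / den
  ## p_hat at the optimum from the steady-state quadratic (+ branch)
  b <- (1 - alpha_opt) * E_M - alpha_opt
  p_opt <- (b + sqrt(b^2 + 4 * alpha_opt * (1 - alpha_opt) * E_M * K)) /
    (2 * alpha_opt)
  list(alpha_opt = alpha_opt, mu_hat_opt = mu_opt,
       p_hat_opt = p_opt, r_hat_opt = alpha_opt)
}

#' Growth-optimal allocation in dimensional parameters
#'
#' `alpha_opt* = (e_M + sqrt(K e_M k_R)) / (e_M + 2 sqrt(K e_M k_R) + k_R)`
#' with the maximal growth rate `mu_opt* = k_R * mu_hat_opt*` \[1/h\].
#' Identical to [optimal_allocation_env()] evaluated at `E_M = e_M / k_R`.
#'
#' @param e_M nutrient efficiency \[1/h\]. Vectorized.
#' @param k_R gene-expression rate constant \[1/h\].
#' @param K dimensionless half-saturation (`beta * K_R`).
#' @return List with `alpha_opt` and `mu_opt` \[1/h\].
#' @export
optimal_allocation_dim <- function(e_M, k_R, K) {
  nd <- optimal_allocation_env(e_M / k_R, K)
  list(alpha_opt = nd$alpha_opt, mu_opt = k_R * nd$mu_hat_opt)
}

#' Optimal steady-state curve in the phase plane
#'
#' The locus of growth-optimal steady states expressed as a function of
#' the precursor abundance:
#' `g(p_hat) = p_hat (K + p_hat) / (p_hat^2 + 2 K p_hat + K)`, so that
#' `g(p_hat_opt*(E_M)) = alpha_opt*(E_M)` for every environment. The
#' corresponding optimal growth rate is
#' `mu_hat_opt* = p_hat^2 / (p_hat^2 + 2 K p_hat + K)`
#' (see [optimal_curve_mu()]). `g` is strictly increasing from 0 to 1.
#'
#' @param p_hat precursor abundance (>= 0). Vectorized.
#' @param K dimensionless half-saturation constant.
#' @return Allocation value(s) in \[0, 1).
#' @export
optimal_curve_g <- function(p_hat, K) {
  p_hat * (K + p_hat) / (p_hat^2 + 2 * K * p_hat + K)
}

#' @rdname optimal_curve_g
#' @export
optimal_curve_mu <- function(p_hat, K) {
  p_hat^2 / (p_hat^2 + 2 * K * p_hat + K)
}
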