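#' Nutrient-only feedback law
#'
#' Constant allocation computed from the environment input alone:
#' `f(E_M) = (E_M + sqrt(K E_M)) / (E_M + 2 sqrt(K E_M) + 1)`. This is the
#' unique static function of `E_M` that stabilizes the growth-optimal
#' steady state in every constant environment; it coincides with the
#' closed-form optimum of [optimal_allocation_env()].
#'
#' @param E_M dimensionless environment input (>= 0). Vectorized.
#' @param K dimensionless half-saturation constant.
#' @return Allocation in \[0, 1).
#' @export
f_nutrient <- function(E_M, K) {
  if (any(E_M < 0)) stop("E_M must be nonnegative")
  s <- sqrt(K * E_M)
  (E_M + s) / (E_M + 2 * s + 1)
}

#' Michaelis-Menten approximation of the nutrient-only law
#'
#' `alpha = E_M / (E_M + K_mE)`: a biochemically plausible stand-in for
#' [f_nutrient()], e.g. a transcription factor activated by a metabolite
#' whose level tracks nutrient influx.
#'
#' @param E_M environment input (>= 0). Vectorized.
#' @param K_mE half-saturation constant (> 0); see
#'   [fit_half_saturation()] and [default_strategy_constants()].
#' @return Allocation in \[0, 1).
#' @export
f_mm_approx <- function(E_M, K_mE) {
  if (K_mE <= 0) stop("K_mE must be strictly positive")
  E_M / (E_M + K_mE)
}

#' Hill approximation of the precursor-only law
#'
#' `alpha = p_hat^2 / (p_hat^2 + K_mp^2)`: a cooperative (Hill
#' coefficient 2) read-out of the precursor concentration approximating
#' the exact optimal curve [optimal_curve_g()].
#'
#' @param p_hat precursor abundance (>= 0). Vectorized.
#' @param K_mp half-saturation constant (> 0).
#' @return Allocation in \[0, 1).
#' @export
g_hill_approx <- function(p_hat, K_mp) {
  if (K_mp <= 0) stop("K_mp must be strictly positive")
  p_hat^2 / (p_hat^2 + K_mp^2)
}

#' On-off feedback law
#'
#' Discontinuous two-variable law: `alpha = 0` above the optimal
#' steady-state curve (`r_hat > g(p_hat)`), `alpha = 1` below it, and
#' `alpha = alpha_opt*` at the growth-optimal steady state itself
#' (equality tested within the relative tolerance `eps_point`).
#'
#' @param p_hat,r_hat state coordinates. Vectorized (recycled).
#' @param params a [nondim_params()] object (supplies `K` and, through
#'   `E_M`, the optimal point).
#' @param optimal_point optional list with `p_hat_opt`, `r_hat_opt`,
#'   `alpha_opt`; computed from `params` when omitted.
#' @param eps_point relative tolerance for state equality with the
#'   optimal point.
#' @return Allocation value(s) in `{0, 1, alpha_opt*}`.
#' @export
h_onoff <- function(p_hat, r_hat, params, optimal_point = NULL,
                    eps_point = selfrep_tolerances()$eps_point) {
  params <- as_nondim(params)
  if (is.null(optimal_point))
    optimal_point <- optimal_allocation_env(params$E_M, params$K)
  g <- optimal_curve_g(p_hat, params$K)
  alpha <- ifelse(r_hat > g, 0, 1)
  at_opt <- abs(p_hat - optimal_point$p_hat_opt) <=
    eps_point * max(optimal_point$p_hat_opt, 1) &
    abs(r_hat - optimal_point$r_hat_opt) <=
    eps_point * max(optimal_point$r_hat_opt, 1)
  alpha[at_opt] <- optimal_point$alpha_opt
  alpha
}

#' Smooth surrogate of the on-off law
#'
#' Continuous approximation used for numerical integration:
#' `alpha = g(p_hat)^n / (g(p_hat)^n + r_hat^n)` with a high Hill
#' exponent (default `n = 100`). Evaluated in log space,
#' `alpha = 1 / (1 + exp(n * (log r_hat - log g(p_hat))))`, to avoid
#' underflow of the 100th powers. When `r_hat = g(p_hat)` the value is
#' 0.5 by the equal-powers limit; the degenerate corner
#' `r_hat = g(p_hat) = 0` is defined as 0.5 by continuity.
#'
#' @inheritParams h_onoff
#' @param n Hill exponent of the surrogate (default 100).
#' @return Allocation value(s) in (0, 1).
#' @export
h_smooth <- function(p_hat, r_hat, params, n = 100) {
  params <- as_nondim(params)
  g <- optimal_curve_g(p_hat, params$K)
  out <- rep(0.5, length.out = max(length(p_hat), length(r_hat)))
  g <- rep(g, length.out = length(out))
  r <- rep(r_hat, length.out = length(out))
  pos <- g > 0 & r > 0
  out[pos] <- stats::plogis(n * (log(g[pos]) - log(r[pos])))
  out[g == 0 & r > 0] <- 0
  out[g > 0 & r == 0] <- 1
  out
}

#' Fit a half-saturation constant to a target response curve
#'
#' Least-squares calibration of the single constant of an approximate
#' feedback law (e.g. `K_mE` of [f_mm_approx()] or `K_mp` of
#' [g_hill_approx()]) against a target curve evaluated on a grid.
#' Deterministic given the grid.
#'
#' @param target function of one variable: the curve to approximate.
#' @param approx function `(x, constant)`: the approximating family.
#' @param domain numeric range `c(lo, hi)` over which to fit.
#' @param n_grid number of evenly spaced grid points (default 400).
#' @param interval search interval for the constant.
#' @return The fitted positive constant (scalar).
#' @export
fit_half_saturation <- function(target, approx, domain, n_grid = 400,
                                interval = c(1e-6, 100)) {
  x <- seq(domain[1], domain[2], length.out = n_grid)
  y <- target(x)
  loss <- function(k) sum((approx(x, k) - y)^2)
  stats::optimize(loss, interval = interval, tol = 1e-12)$minimum
}

#' Default fitted constants of the approximate feedback laws
#'
#' `K_mE` is fitted over `E_M` in \[0.01, 10\] and `K_mp` over `p_hat`
#' in \[0, 1\] by [fit_half_saturation()], for a given `K`. Values are
#' memoized per `K` within a session.
#'
#' @param K dimensionless half-saturation constant of the model.
#' @return Named list with `K_mE` and `K_mp`.
#' @export
default_strategy_constants <- local({
  cache <- list()
  function(K = 0.003) {
    key <- format(K, digits = 15)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- list(
      K_mE = fit_half_saturation(function(x) f_nutrient(x, K), f_mm_approx,
                                 domain = c(0.01, 10)),
      K_mp = fit_half_saturation(function(x) optimal_curve_g(x, K),
                                 g_hill_approx, domain = c(0, 1))
    )
    cache[[key]] <<- out
    out
  }
})

#' Specify a feedback allocation strategy
#'
#' Bundles a strategy kind with its constants for use in closed-loop
#' simulation ([integrate_closed_loop()]) and response-surface analysis
#' ([response_surface()]).
#'
#' Kinds: `"nutrient_only"` (exact law [f_nutrient()]), `"mm_approx"`,
#' `"precursor_only"` (exact curve [optimal_curve_g()]), `"hill_approx"`,
#' `"on_off"` (discontinuous [h_onoff()]; for simulation the smooth
#' surrogate is substituted automatically), `"on_off_smooth"`
#' ([h_smooth()]), `"constant"` (fixed allocation), and `"custom"`
#' (a user function `constants$fn(p_hat, r_hat, params)` returning the
#' allocation, e.g. a feedback law built on an estimated switching
#' curve).
#'
#' @param kind strategy kind, see Details.
#' @param constants named list of constants (`K_mE`, `K_mp`, `n`,
#'   `alpha`, `fn`); missing approximation constants are filled from
#'   [default_strategy_constants()] at evaluation time.
#' @return Object of class `strategy_spec`.
#' @export
strategy <- function(kind = c("nutrient_only", "precursor_only", "on_off",
                              "on_off_smooth", "mm_approx", "hill_approx",
                              "constant", "custom"),
                     constants = list()) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (is.null(constants$alpha))
      stop("constant strategy requires constants$alpha")
    if (constants$alpha < 0 || constants$alpha > 1)
      stop("fixed alpha must lie in [0, 1]")
  }
  if (kind == "custom" && !is.function(constants$fn))
    stop("custom strategy requires a function constants$fn")
  if (!is.null(constants$K_mE) && constants$K_mE <= 0)
    stop("K_mE must be positive")
  if (!is.null(constants$K_mp) && constants$K_mp <= 0)
    stop("K_mp must be positive")
  structure(list(kind = kind, constants = constants),
            class = "strategy_spec")
}

#' Evaluate a strategy's allocation at a state
#'
#' Static feedback: the allocation is a function of the current state
#' (and the environment input), with no memory.
#'
#' @param spec a [strategy()] object.
#' @param p_hat,r_hat state coordinates (vectorized).
#' @param params a [nondim_params()] object.
#' @param smooth_onoff substitute the smooth surrogate for the
#'   discontinuous on-off law (default `FALSE`; simulation sets `TRUE`).
#' @return Allocation value(s) in \[0, 1\].
#' @export
strategy_alpha <- function(spec, p_hat, r_hat, params,
                           smooth_onoff = FALSE) {
  stopifnot(inherits(spec, "strategy_spec"))
  params <- as_nondim(params)
  cst <- spec$constants
  switch(spec$kind,
    nutrient_only = rep(f_nutrient(params$E_M, params$K),
                        length.out = length(p_hat)),
    mm_approx = {
      K_mE <- cst$K_mE %||% default_strategy_constants(params$K)$K_mE
      rep(f_mm_approx(params$E_M, K_mE), length.out = length(p_hat))
    },
    precursor_only = optimal_curve_g(p_hat, params$K),
    hill_approx = {
      K_mp <- cst$K_mp %||% default_strategy_constants(params$K)$K_mp
      g_hill_approx(p_hat, K_mp)
    },
    on_off = if (smooth_onoff)
      h_smooth(p_hat, r_hat, params, n = cst$n %||% 100)
    else h_onoff(p_hat, r_hat, params),
    on_off_smooth = h_smooth(p_hat, r_hat, params, n = cst$n %||% 100),
    constant = rep(cst$alpha, length.out = length(p_hat)),
    custom = cst$fn(p_hat, r_hat, params)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("Allocation strategy: %s", x$kind))
  if (length(x$constants))
    cat(" (", paste(names(x$constants), unlist(x$constants),
                    sep = " = ", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}
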