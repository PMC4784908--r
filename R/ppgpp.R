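#' Allocation as a function of ppGpp concentration
#'
#' Michaelis-Menten inhibition of ribosomal RNA transcription by the
#' alarmone ppGpp: `alpha = K_I / (K_I + ppGpp)`, strictly decreasing in
#' the ppGpp concentration.
#'
#' @param conc ppGpp concentration \[umol/L\] (>= 0). Vectorized.
#' @param K_I inhibition constant \[umol/L\].
#' @return Allocation in (0, 1\].
#' @export
alpha_from_ppgpp <- function(conc, K_I) {
  if (K_I <= 0) stop("K_I must be strictly positive")
  if (any(conc < 0)) stop("ppGpp concentration must be nonnegative")
  K_I / (K_I + conc)
}

## Goldbeter-Koshland balance: fraction u of uncharged tRNA at quasi
## steady state, with uncharging (translation demand) V1 acting on the
## charged pool and recharging capacity V2 acting on the uncharged pool,
## both saturable (zero-order regime for small K1, K2). Internal.
gk_fraction <- function(V1, V2, K1, K2) {
  n <- max(length(V1), length(V2))
  V1 <- rep(V1, length.out = n); V2 <- rep(V2, length.out = n)
  a <- V2 - V1
  b <- V1 * (1 - K2) - V2 * (1 + K1)
  cc <- V1 * K2
  u <- numeric(n)
  for (i in seq_len(n)) {
    if (V1[i] <= 0) { u[i] <- 0; next }
    if (V2[i] <= 0) { u[i] <- 1; next }
    if (abs(a[i]) < 1e-12 * max(V1[i], V2[i])) {
      u[i] <- -cc[i] / b[i]
    } else {
      disc <- sqrt(max(b[i]^2 - 4 * a[i] * cc[i], 0))
      roots <- c((-b[i] + disc) / (2 * a[i]), (-b[i] - disc) / (2 * a[i]))
      ok <- roots[roots >= -1e-12 & roots <= 1 + 1e-12]
      u[i] <- if (length(ok)) min(max(ok[1], 0), 1) else NA_real_
    }
  }
  u
}

#' Reduced ppGpp model constants
#'
#' Quasi-steady-state reduction of ppGpp metabolism: all individual
#' amino-acid pools are lumped into the precursor concentration; tRNA
#' charging is in fast equilibrium with the precursor level, with a
#' cooperative (Hill 2) charging capacity `supply_amp * p_hat^2 /
#' (p_hat^2 + K_t^2)` whose two constants are calibrated once and then
#' frozen by anchoring the capacity to the optimal steady-state curve
#' [optimal_curve_g()] at two points (the optimal precursor abundance
#' for `E_M = 1`, and `p_hat = 1`); the anchoring keeps the capacity
#' strictly below 1, so the switch always falls inside the admissible
#' ribosome range. Translation demand is proportional to the ribosome
#' concentration `r_hat`. The uncharged-tRNA fraction follows from a
#' zero-order charging/consumption balance (Goldbeter-Koshland, with
#' saturation constants `K1`, `K2`), which makes the stalled-ribosome
#' fraction strongly ultrasensitive to the demand/supply imbalance.
#' RelA-driven ppGpp synthesis is proportional to the stalled fraction
#' and degradation is first order, giving
#' `ppGpp = basal + gain * sigma` at quasi steady state. The inhibition
#' constant `K_I` is calibrated so the induced allocation equals the
#' optimal allocation on the curve `r_hat = g(p_hat)` at the optimal
#' precursor abundance for `E_M = 1`.
#'
#' @param params a [nondim_params()] object (supplies `K`; `E_M = 1` is
#'   used only for the `K_I` calibration point).
#' @param K1,K2 saturation constants of the charging balance (default
#'   0.002 each; smaller values sharpen the switch).
#' @param basal basal ppGpp concentration \[umol/L\] (default 10).
#' @param gain maximal RelA-driven ppGpp increment \[umol/L\] (default
#'   1000).
#' @return List of class `ppgpp_params` with `supply_amp`, `K_t`, `K1`,
#'   `K2`, `basal`, `gain`, `K_I`.
#' @export
ppgpp_params <- function(params = nondim_params(1, 0.003),
                         K1 = 0.002, K2 = 0.002,
                         basal = 10, gain = 1000) {
  params <- as_nondim(params)
  K <- params$K
  ## anchor the Hill(2) capacity to the optimal curve at the E_M = 1
  ## optimal precursor abundance p_star and at p_hat = 1: two equations
  ## fix (supply_amp, K_t) exactly and keep supply_amp < 1
  cal <- optimal_allocation_env(1, K)
  p_star <- cal$p_hat_opt
  g_star <- optimal_curve_g(p_star, K)
  g_one <- optimal_curve_g(1, K)
  K_t2 <- p_star^2 * (g_star - g_one) / (p_star^2 * g_one - g_star)
  supply_amp <- g_one * (1 + K_t2)
  pp <- list(supply_amp = supply_amp, K_t = sqrt(K_t2), K1 = K1, K2 = K2,
             basal = basal, gain = gain, K_I = NA_real_, K = K)
  ## calibrate K_I: alpha = alpha_opt* on r_hat = g(p_hat) at p_star
  G <- ppgpp_qss_raw(p_star, g_star, pp)
  pp$K_I <- G * cal$alpha_opt / (1 - cal$alpha_opt)
  structure(pp, class = "ppgpp_params")
}

## ppGpp concentration without class checks (internal).
ppgpp_qss_raw <- function(p_hat, r_hat, pp) {
  supply <- pp$supply_amp * p_hat^2 / (p_hat^2 + pp$K_t^2)
  sigma <- gk_fraction(V1 = r_hat, V2 = supply, K1 = pp$K1, K2 = pp$K2)
  pp$basal + pp$gain * sigma
}

#' Quasi-steady-state ppGpp concentration
#'
#' ppGpp read-out of the cell state: increasing in the ribosome
#' concentration at fixed precursor level (more ribosomes competing for
#' the same charging capacity means more stalling) and decreasing in
#' the precursor level at fixed ribosome concentration; approaches the
#' basal concentration when precursors saturate the charging system.
#'
#' @param p_hat,r_hat state coordinates (vectorized).
#' @param pp a [ppgpp_params()] object.
#' @return ppGpp concentration(s) \[umol/L\].
#' @export
ppgpp_qss <- function(p_hat, r_hat, pp) {
  stopifnot(inherits(pp, "ppgpp_params"))
  if (any(p_hat < 0) || any(r_hat < 0)) stop("state must be nonnegative")
  ppgpp_qss_raw(p_hat, r_hat, pp)
}

#' Allocation response surface on a phase-plane grid
#'
#' Evaluates the allocation of either a feedback [strategy()] or the
#' ppGpp read-out (a [ppgpp_params()] object) on a `p_hat` x `r_hat`
#' grid, in long format.
#'
#' @param x a `strategy_spec` or `ppgpp_params` object.
#' @param p_grid,r_grid grid coordinates (defaults: 101 points on
#'   \[0, 1\] each).
#' @param params a [nondim_params()] object (used for strategies).
#' @return data.frame with columns `p_hat`, `r_hat`, `alpha`, `source`.
#' @export
response_surface <- function(x, p_grid = seq(0, 1, length.out = 101),
                             r_grid = seq(0, 1, length.out = 101),
                             params = nondim_params(1, 0.003)) {
  grid <- expand.grid(p_hat = p_grid, r_hat = r_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (inherits(x, "strategy_spec")) {
    alpha <- strategy_alpha(x, grid$p_hat, grid$r_hat, params)
    src <- x$kind
  } else if (inherits(x, "ppgpp_params")) {
    alpha <- alpha_from_ppgpp(ppgpp_qss(grid$p_hat, grid$r_hat, x), x$K_I)
    src <- "ppgpp"
  } else stop("x must be a strategy_spec or ppgpp_params object")
  data.frame(p_hat = grid$p_hat, r_hat = grid$r_hat, alpha = alpha,
             source = src)
}

#' Agreement fraction between two response surfaces
#'
#' Fraction of grid points, excluding a band of half-width `delta`
#' around the optimal steady-state curve `r_hat = g(p_hat)`, where both
#' surfaces fall on the same side of `alpha = 0.5`. Quantifies the
#' visual similarity between the on-off strategy and the ppGpp
#' read-out.
#'
#' @param surface_a,surface_b long-format surfaces from
#'   [response_surface()] on identical grids.
#' @param delta half-width of the excluded band around the curve
#'   (default 0.02).
#' @param K dimensionless half-saturation constant of the model
#'   (default 0.003).
#' @return Agreement fraction in \[0, 1\].
#' @export
compare_surfaces <- function(surface_a, surface_b, delta = 0.02,
                             K = 0.003) {
  if (nrow(surface_a) != nrow(surface_b) ||
      any(abs(surface_a$p_hat - surface_b$p_hat) > 1e-12) ||
      any(abs(surface_a$r_hat - surface_b$r_hat) > 1e-12))
    stop("surfaces must be evaluated on identical grids")
  g <- optimal_curve_g(surface_a$p_hat, K)
  keep <- abs(surface_a$r_hat - g) >= delta
  mean((surface_a$alpha[keep] > 0.5) == (surface_b$alpha[keep] > 0.5))
}
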