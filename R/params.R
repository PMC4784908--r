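#' Dimensional self-replicator parameters
#'
#' Rate and affinity constants of the two macroreactions of the
#' self-replicator: nutrient conversion into precursors by the metabolic
#' machinery, and precursor conversion into macromolecules by the
#' gene-expression machinery. The substrate term is folded into the
#' effective nutrient efficiency `e_M`, assumed constant over the interval
#' of interest.
#'
#' @param e_M nutrient efficiency rate constant \[1/h\] (environment input).
#' @param k_R gene-expression rate constant \[1/h\] (translation efficiency).
#' @param K_R half-saturation constant of macromolecule synthesis with
#'   respect to the precursor concentration \[g/L\].
#' @param beta inverse cytoplasmic density \[L/g\]; volume is
#'   `beta * (M + R)`.
#' @return Object of class `dim_params`.
#' @examples
#' dim_params()  # reference E. coli-like parameterization
#' @export
dim_params <- function(e_M = 3.6, k_R = 3.6, K_R = 1, beta = 0.003) {
  vals <- c(e_M = e_M, k_R = k_R, K_R = K_R, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dimensional parameters must be finite and strictly positive")
  structure(as.list(vals), class = "dim_params")
}

#' Nondimensional self-replicator parameters
#'
#' The rescaled model depends on two constants only: the dimensionless
#' environment input `E_M = e_M / k_R` and the dimensionless
#' half-saturation `K = beta * K_R`.
#'
#' @param E_M dimensionless environment input (> 0).
#' @param K dimensionless half-saturation constant (> 0).
#' @return Object of class `nondim_params`.
#' @export
nondim_params <- function(E_M = 1, K = 0.003) {
  if (!is.finite(E_M) || !is.finite(K) || E_M <= 0 || K <= 0)
    stop("E_M and K must be finite and strictly positive")
  structure(list(E_M = E_M, K = K), class = "nondim_params")
}

#' Nondimensionalize dimensional parameters
#'
#' Applies the rescaling `p_hat = beta * p`, `r_hat = beta * r`,
#' `t_hat = k_R * t`, giving `E_M = e_M / k_R` and `K = beta * K_R`.
#'
#' @param params a [dim_params()] object.
#' @return List with `params` (a [nondim_params()] object) and
#'   `time_scale` (the factor `k_R` converting hours to dimensionless
#'   time; divide `t_hat` by it to recover hours).
#' @examples
#' nondimensionalize(dim_params(3.6, 3.6, 1, 0.003))  # E_M = 1, K = 0.003
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "dim_params"))
  list(
    params = nondim_params(E_M = params$e_M / params$k_R,
                           K   = params$beta * params$K_R),
    time_scale = params$k_R
  )
}

#' @export
print.dim_params <- function(x, ...) {
  cat("Self-replicator parameters (dimensional):\n")
  cat(sprintf("  e_M = %g /h, k_R = %g /h, K_R = %g g/L, beta = %g L/g\n",
              x$e_M, x$k_R, x$K_R, x$beta))
  invisible(x)
}

#' @export
print.nondim_params <- function(x, ...) {
  cat(sprintf("Self-replicator parameters (nondimensional): E_M = %g, K = %g\n",
              x$E_M, x$K))
  invisible(x)
}

## Coerce anything parameter-like to nondim_params (internal).
as_nondim <- function(params) {
  if (inherits(params, "nondim_params")) return(params)
  if (inherits(params, "dim_params")) return(nondimensionalize(params)$params)
  if (is.list(params) && all(c("E_M", "K") %in% names(params)))
    return(nondim_params(params$E_M, params$K))
  stop("cannot interpret 'params' as self-replicator parameters")
}
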