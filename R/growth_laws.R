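#' Predicted growth-law curve across media
#'
#' Steady-state relation between the maximal growth rate and the optimal
#' allocation as the nutrient efficiency `e_M` varies at fixed
#' translation efficiency `k_R`: the model's counterpart of the
#' first bacterial growth law (ribosomal fraction versus growth rate
#' across media), quasi-linear at high growth rates.
#'
#' @param k_R gene-expression rate constant \[1/h\].
#' @param K dimensionless half-saturation constant.
#' @param e_M vector of nutrient efficiencies \[1/h\].
#' @return data.frame with columns `e_M`, `mu_opt` \[1/h\], `alpha_opt`.
#' @export
predict_growth_law <- function(k_R, K, e_M) {
  opt <- optimal_allocation_dim(e_M, k_R, K)
  data.frame(e_M = e_M, mu_opt = opt$mu_opt, alpha_opt = opt$alpha_opt)
}

#' Predicted translation-inhibitor series
#'
#' Second growth law: at fixed nutrient efficiency, decreasing the
#' translation efficiency `k_R` (e.g. by chloramphenicol) lowers the
#' maximal growth rate while raising the optimal ribosomal allocation.
#'
#' @param e_M fixed nutrient efficiency \[1/h\].
#' @param k_R vector of translation efficiencies \[1/h\].
#' @param K dimensionless half-saturation constant.
#' @return data.frame with columns `k_R`, `mu_opt`, `alpha_opt`.
#' @export
chloramphenicol_series <- function(e_M, k_R, K) {
  opt <- optimal_allocation_dim(e_M, k_R, K)
  data.frame(k_R = k_R, mu_opt = opt$mu_opt, alpha_opt = opt$alpha_opt)
}

#' Generate a synthetic growth-law dataset
#'
#' Emulates the design of classical growth-law measurements: several
#' growth media (different `e_M`) crossed with several doses of a
#' translation inhibitor (modelled as multiplicative reductions of
#' `k_R`), each point being the growth-optimal steady state of the
#' model, observed through the RNA/protein mass ratio
#' `ratio = alpha_opt / gamma` with multiplicative Gaussian measurement
#' noise on both coordinates. Deterministic given `seed`; noiseless at
#' `sigma = 0`.
#'
#' @param k_R true translation efficiency \[1/h\] (default 2.23).
#' @param gamma true RNA/protein-to-allocation conversion factor
#'   (default 0.76).
#' @param e_M_media named or unnamed vector of per-medium nutrient
#'   efficiencies \[1/h\] (default 6 media spanning poor to rich).
#' @param dose_factors multiplicative `k_R` reductions per inhibitor
#'   dose, in (0, 1\] with the first equal to 1 (default 5 doses).
#' @param K dimensionless half-saturation constant (default 0.003).
#' @param sigma multiplicative noise standard deviation (default 0.05).
#' @param seed RNG seed.
#' @return data.frame (class `growth_law_dataset`) with columns
#'   `medium`, `dose`, `growth_rate` \[1/h\], `rna_protein_ratio`, `sd`.
#' @export
generate_synthetic_dataset <- function(k_R = 2.23, gamma = 0.76,
                                       e_M_media = c(0.5, 0.9, 1.57, 2.5,
                                                     3.6, 4.76),
                                       dose_factors = c(1, 0.8, 0.6,
                                                        0.45, 0.3),
                                       K = 0.003, sigma = 0.05,
                                       seed = 1L) {
  if (any(dose_factors <= 0 | dose_factors > 1) || dose_factors[1] != 1)
    stop("dose_factors must lie in (0, 1] with the first equal to 1")
  if (is.null(names(e_M_media)))
    names(e_M_media) <- paste0("medium", seq_along(e_M_media))
  grid <- expand.grid(medium = names(e_M_media),
                      dose = seq_along(dose_factors) - 1L,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  e <- e_M_media[grid$medium]
  keff <- k_R * dose_factors[grid$dose + 1L]
  opt <- optimal_allocation_dim(e, keff, K)
  mu <- opt$mu_opt
  ratio <- opt$alpha_opt / gamma
  set.seed(seed)
  if (sigma > 0) {
    mu <- mu * (1 + stats::rnorm(length(mu), 0, sigma))
    ratio <- ratio * (1 + stats::rnorm(length(ratio), 0, sigma))
  }
  out <- data.frame(medium = grid$medium, dose = grid$dose,
                    growth_rate = mu, rna_protein_ratio = ratio,
                    sd = sigma * opt$alpha_opt / gamma)
  structure(out, class = c("growth_law_dataset", "data.frame"),
            truth = list(k_R = k_R, gamma = gamma, e_M = e_M_media,
                         dose_factors = dose_factors, K = K,
                         sigma = sigma, seed = seed))
}

#' Differential evolution optimizer
#'
#' Compact Storn-Price DE/rand/1/bin global optimizer with box
#' constraints, used for growth-law fitting. Deterministic given
#' `seed`.
#'
#' @param fn objective to minimize (takes a numeric vector).
#' @param lower,upper bounds (equal length).
#' @param NP population size (default `15 * length(lower)`).
#' @param maxiter number of generations (default 500).
#' @param F mutation weight (default 0.8).
#' @param CR crossover probability (default 0.9).
#' @param seed RNG seed (default 0).
#' @param tol early stop when the population objective spread falls
#'   below `tol` (default 1e-12).
#' @return List with `par`, `value`, `iterations`.
#' @export
de_optim <- function(fn, lower, upper, NP = 15 * length(lower),
                     maxiter = 500, F = 0.8, CR = 0.9, seed = 0,
                     tol = 1e-12) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  set.seed(seed)
  pop <- matrix(stats::runif(NP * d, lower, upper), nrow = NP, ncol = d,
                byrow = TRUE)
  cost <- apply(pop, 1, fn)
  for (it in seq_len(maxiter)) {
    idx <- replicate(NP, sample.int(NP, 3))
    r1 <- pop[idx[1, ], , drop = FALSE]
    r2 <- pop[idx[2, ], , drop = FALSE]
    r3 <- pop[idx[3, ], , drop = FALSE]
    trial <- r1 + F * (r2 - r3)
    cross <- matrix(stats::runif(NP * d) < CR, NP, d)
    jrand <- cbind(seq_len(NP), sample.int(d, NP, replace = TRUE))
    cross[jrand] <- TRUE
    trial[!cross] <- pop[!cross]
    ## reflect out-of-bounds components back into the box
    lo <- matrix(lower, NP, d, byrow = TRUE)
    hi <- matrix(upper, NP, d, byrow = TRUE)
    trial <- pmin(pmax(trial, lo), hi)
    tcost <- apply(trial, 1, fn)
    better <- tcost < cost
    pop[better, ] <- trial[better, ]
    cost[better] <- tcost[better]
    if (max(cost) - min(cost) < tol) break
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], iterations = it)
}

## Per-point inversion of the dimensional optimum: given observed growth
## rate mu and effective k_R, solve for e_M and the implied alpha_opt
## (internal; returns list(e_M, alpha), NA where mu >= k_eff).
invert_optimum <- function(mu, k_eff, K) {
  b <- sqrt(k_eff)
  feasible <- mu > 0 & mu < k_eff
  s <- rep(NA_real_, length(mu))
  disc <- mu^2 * K + (k_eff - mu) * mu
  s[feasible] <- (mu[feasible] * sqrt(K) * b[feasible] +
                  b[feasible] * sqrt(disc[feasible])) /
    (k_eff[feasible] - mu[feasible])
  e <- s^2
  skb <- sqrt(K) * s * b
  alpha <- (e + skb) / (e + 2 * skb + k_eff)
  list(e_M = e, alpha = alpha)
}

#' Fit the self-replicator growth laws to data
#'
#' Estimates the translation efficiency `k_R`, the RNA/protein
#' conversion factor `gamma`, per-medium nutrient efficiencies `e_M`,
#' and (when several inhibitor doses are present) per-dose `k_R`
#' reduction factors, from a table of (growth rate, RNA/protein ratio)
#' measurements, with `K` fixed.
#'
#' The default (`loss = "joint"`) treats the per-medium nutrient
#' efficiencies as shared free parameters across inhibitor doses and
#' minimizes the summed squared relative residuals of both predicted
#' coordinates (growth rate and ratio); sharing `e_M` across the dose
#' series of a medium is what makes `k_R` identifiable in the presence
#' of measurement noise. `gamma` is profiled out in closed form. The
#' alternative `loss = "ratio_inversion"` inverts `e_M` per point from
#' the observed growth rate and scores residuals in the ratio
#' coordinate only (fewer search dimensions, but growth-rate noise is
#' absorbed into the per-point inversions). The global search uses
#' differential evolution followed by a deterministic quasi-Newton
#' polish.
#'
#' @param dataset a `growth_law_dataset` or data.frame with columns
#'   `medium`, `dose`, `growth_rate`, `rna_protein_ratio`.
#' @param K fixed dimensionless half-saturation constant (default
#'   0.003).
#' @param loss `"joint"` (default) or `"ratio_inversion"`, see Details.
#' @param bounds_k_R search bounds for `k_R` \[1/h\].
#' @param bounds_e_M search bounds for the per-medium `e_M` \[1/h\].
#' @param de_control list of [de_optim()] settings (`NP`, `maxiter`,
#'   `seed`, ...).
#' @return Object of class `growth_law_fit`: list with `k_R`, `gamma`,
#'   `e_M` (named per medium), `dose_factors`, `loss`, `seed`.
#' @export
fit_growth_laws <- function(dataset, K = 0.003,
                            loss = c("joint", "ratio_inversion"),
                            bounds_k_R = c(0.1, 20),
                            bounds_e_M = c(0.01, 50),
                            de_control = list()) {
  loss <- match.arg(loss)
  req <- c("medium", "dose", "growth_rate", "rna_protein_ratio")
  if (!all(req %in% names(dataset)))
    stop("dataset must have columns ", paste(req, collapse = ", "))
  media <- unique(as.character(dataset$medium))
  if (length(media) < 2)
    stop("underdetermined: at least 2 media are required")
  mu <- dataset$growth_rate
  ratio <- dataset$rna_protein_ratio
  if (any(mu <= 0) || any(ratio <= 0))
    stop("growth rates and ratios must be positive")
  doses <- sort(unique(dataset$dose))
  n_free <- length(doses) - 1L          # first dose factor fixed at 1
  dose_idx <- match(dataset$dose, doses)
  med_idx <- match(as.character(dataset$medium), media)
  n_med <- length(media)

  profile_gamma <- function(a) {        # relative ratio residuals
    x <- a / ratio
    cc <- sum(x) / sum(x^2)             # profiled 1/gamma
    list(res = cc * x - 1, gamma = 1 / cc)
  }
  if (loss == "joint") {
    eval_theta <- function(theta) {
      k_R <- theta[1]
      e_M <- theta[1 + seq_len(n_med)]
      d <- c(1, theta[-seq_len(1 + n_med)])
      k_eff <- k_R * d[dose_idx]
      opt <- optimal_allocation_dim(e_M[med_idx], k_eff, K)
      pg <- profile_gamma(opt$alpha_opt)
      list(loss = sum((opt$mu_opt / mu - 1)^2) + sum(pg$res^2),
           gamma = pg$gamma, e_M = setNames(e_M, media))
    }
    lower <- c(bounds_k_R[1], rep(bounds_e_M[1], n_med), rep(0.01, n_free))
    upper <- c(bounds_k_R[2], rep(bounds_e_M[2], n_med), rep(1, n_free))
  } else {
    eval_theta <- function(theta) {
      k_R <- theta[1]
      d <- c(1, theta[-1])
      k_eff <- k_R * d[dose_idx]
      inv <- invert_optimum(mu, k_eff, K)
      if (any(!is.finite(inv$alpha)) ||
          any(inv$e_M < bounds_e_M[1] | inv$e_M > bounds_e_M[2]))
        return(list(loss = 1e6, gamma = NA_real_, e_M = NULL))
      pg <- profile_gamma(inv$alpha)
      list(loss = sum(pg$res^2), gamma = pg$gamma,
           e_M = tapply(inv$e_M, med_idx, mean)[as.character(seq_len(n_med))])
    }
    lower <- c(bounds_k_R[1], rep(0.01, n_free))
    upper <- c(bounds_k_R[2], rep(1, n_free))
  }
  fn <- function(theta) eval_theta(theta)$loss
  ctrl <- modifyList(list(NP = 15 * length(lower), maxiter = 500,
                          seed = 0), de_control)
  de <- de_optim(fn, lower, upper, NP = ctrl$NP,
                 maxiter = ctrl$maxiter, seed = ctrl$seed)
  polish <- stats::optim(de$par, fn, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(maxit = 1000, factr = 1,
                                        ndeps = rep(1e-7, length(de$par))))
  best <- if (polish$value < de$value) polish else de
  fin <- eval_theta(best$par)
  e_M <- fin$e_M
  if (!is.null(e_M)) names(e_M) <- media
  d_fit <- c(1, utils::tail(best$par, n_free))
  structure(list(
    k_R = best$par[1], gamma = fin$gamma, e_M = e_M,
    dose_factors = setNames(d_fit, paste0("dose", doses)),
    loss = best$value, loss_kind = loss, seed = ctrl$seed, K = K
  ), class = "growth_law_fit")
}

#' @export
print.growth_law_fit <- function(x, ...) {
  cat(sprintf("Growth-law fit: k_R = %.4g /h, gamma = %.4g, loss = %.4g\n",
              x$k_R, x$gamma, x$loss))
  cat("  e_M per medium [1/h]:\n")
  print(round(x$e_M, 4))
  cat("  dose factors:\n")
  print(round(x$dose_factors, 4))
  invisible(x)
}
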