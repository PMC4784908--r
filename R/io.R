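#' Load a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension) describing
#' model parameters, an optional scenario, strategy, solver preset and
#' seed. Exactly one of the two parameter groups must be present:
#' dimensional (`e_M`, `k_R`, `K_R`, `beta`) or nondimensional (`E_M`,
#' `K`). Missing nondimensional values default to the reference
#' parameterization `E_M = 1`, `K = 0.003`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return List of class `run_config` with elements `params` (a
#'   [nondim_params()]), `time_scale` (k_R in 1/h, or `NA` for
#'   nondimensional input), `scenario`, `strategy`, `solver`, `seed`,
#'   `raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml or .json file")
  dim_keys <- c("e_M", "k_R", "K_R", "beta")
  nd_keys <- c("E_M", "K")
  has_dim <- any(dim_keys %in% names(raw))
  has_nd <- any(nd_keys %in% names(raw))
  if (has_dim && has_nd)
    stop("config error: both parameter groups present; give either ",
         paste(dim_keys, collapse = "/"), " or ",
         paste(nd_keys, collapse = "/"))
  if (has_dim) {
    missing_keys <- setdiff(dim_keys, names(raw))
    if (length(missing_keys))
      stop("config error: missing dimensional key(s): ",
           paste(missing_keys, collapse = ", "))
    dp <- dim_params(raw$e_M, raw$k_R, raw$K_R, raw$beta)
    nd <- nondimensionalize(dp)
    params <- nd$params; time_scale <- nd$time_scale
  } else {
    params <- nondim_params(raw$E_M %||% 1, raw$K %||% 0.003)
    time_scale <- NA_real_
  }
  strat <- NULL
  if (!is.null(raw$strategy))
    strat <- strategy(raw$strategy$kind %||% raw$strategy,
                      constants = raw$strategy$constants %||% list())
  structure(list(
    params = params, time_scale = time_scale,
    scenario = raw$scenario, strategy = strat,
    solver = raw$solver, seed = raw$seed %||% 0L, raw = raw
  ), class = "run_config")
}

#' Write / read a trajectory as CSV
#'
#' Plain CSV with header `t_hat,p_hat,r_hat,alpha,mu_hat,log_vol`
#' (comma separator, `.` decimal, UTF-8). Reading validates the header,
#' rejects ragged rows and requires strictly increasing times.
#'
#' @param traj a [replicator_trajectory()].
#' @param path output path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns a [replicator_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "replicator_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  cols <- c("t_hat", "p_hat", "r_hat", "alpha", "mu_hat", "log_vol")
  lines <- readLines(path)
  nfield <- lengths(strsplit(lines, ",", fixed = TRUE))
  if (any(nfield != nfield[1]))
    stop("ragged rows in trajectory file: ", path)
  df <- utils::read.csv(path)
  if (!identical(names(df), cols))
    stop("trajectory file must have header ", paste(cols, collapse = ","))
  if (any(diff(df$t_hat) <= 0))
    stop("trajectory times must be strictly increasing")
  replicator_trajectory(df$t_hat, df$p_hat, df$r_hat, df$alpha,
                        df$mu_hat, df$log_vol)
}

#' Write a JSON run report
#'
#' Collects the scalar results of an analysis run (objective values,
#' final biomass ratios, arc structure, fit results) together with
#' seed/solver metadata into a JSON summary.
#'
#' @param artifacts named list of results; `ocp_solution`,
#'   `growth_law_fit` and [biomass_ratio()] outputs are summarized,
#'   scalars and vectors pass through.
#' @param path output path.
#' @param seed seed recorded in the report.
#' @param solver optional solver/preset description.
#' @return The report list, invisibly; written as JSON to `path`.
#' @export
run_report <- function(artifacts, path, seed = 0L, solver = NULL) {
  summarize <- function(x) {
    if (inherits(x, "ocp_solution")) {
      arcs <- classify_arcs(x)
      list(objective = x$objective, arcs = arcs$arcs,
           switch_times = arcs$switch_times,
           n_alternations = arcs$n_alternations,
           terminal_violation = x$terminal_violation)
    } else if (inherits(x, "growth_law_fit")) {
      list(k_R = x$k_R, gamma = x$gamma, e_M = as.list(x$e_M),
           dose_factors = as.list(x$dose_factors), loss = x$loss,
           seed = x$seed)
    } else if (is.list(x) && all(c("ratio", "final") %in% names(x))) {
      list(final_ratio = x$final)
    } else x
  }
  report <- list(
    metadata = list(package = "selfrep",
                    version = as.character(utils::packageVersion("selfrep")),
                    seed = seed, solver = solver,
                    timestamp = format(Sys.time(), tz = "UTC")),
    results = lapply(artifacts, summarize)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
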