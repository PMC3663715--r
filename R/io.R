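#' Read a cell-population time course from delimited text
#'
#' Expects a header with a `time_hr` column and either a `mean` column,
#' replicate columns `rep1..repN`, or both.  When only replicates are
#' present their row means are computed; replicate columns are retained
#' either way.  Validation failures (non-increasing times, non-positive
#' intensities, missing columns) raise descriptive errors naming the
#' offending row.
#'
#' @param path Path to a CSV file.
#' @return An [llv_timeseries].
#' @export
read_timeseries <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  timeseries_from_frame(df, path)
}

timeseries_from_frame <- function(df, what) {
  if (!"time_hr" %in% names(df))
    stop("'", what, "': missing required column 'time_hr'")
  repcols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  if (!"mean" %in% names(df) && length(repcols) == 0L)
    stop("'", what, "': need a 'mean' column or replicate columns rep1..repN")
  times <- df$time_hr
  if (any(!is.finite(times)))
    stop("'", what, "': non-numeric time in row ",
         which(!is.finite(times))[1L])
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("'", what, "': times not strictly increasing at row ",
         which(diff(times) <= 0)[1L] + 1L)
  reps <- if (length(repcols)) as.matrix(df[repcols]) else NULL
  if (!is.null(reps)) {
    bad <- which(apply(reps, 1L, function(v) any(!is.finite(v) | v <= 0)))
    if (length(bad))
      stop("'", what, "': non-positive replicate intensity in row ", bad[1L],
           " (relative error is undefined at zero)")
  }
  if ("mean" %in% names(df)) {
    bad <- which(!is.finite(df$mean) | df$mean <= 0)
    if (length(bad))
      stop("'", what, "': non-positive mean intensity in row ", bad[1L],
           " (relative error is undefined at zero)")
    llv_timeseries(times, values = df$mean, replicates = reps)
  } else {
    llv_timeseries(times, replicates = reps)
  }
}

#' Write a time course to CSV at full precision
#'
#' Columns `time_hr`, `rep1..repN` (when replicates are present) and
#' `mean`, written with 17 significant digits so that
#' `read_timeseries(write_timeseries(x))` reproduces the numbers
#' exactly.
#'
#' @param x An [llv_timeseries].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "llv_timeseries"))
  df <- as.data.frame(x)
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns `time_hr`, `x`, `y`.
#'
#' @param traj An `"llv_trajectory"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "llv_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a fit to JSON
#'
#' Stores the estimated parameters, free-parameter names, loss/fitness,
#' optimisation history, evaluation count, seed, step and the fitted
#' data, so a fit is fully reconstructable (and auditable) from the
#' file.
#'
#' @param fit An `"llv_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "llv_fit"))
  obj <- list(
    model = fit$model,
    params = as.list(unclass(fit$params)),
    free = fit$free,
    loss = fit$loss, fitness = fit$fitness,
    history = fit$history, evaluations = fit$evaluations,
    seed = fit$seed, step = fit$step,
    data = as.data.frame(fit$data),
    config = list(population = fit$control$population,
                  generations = fit$control$generations,
                  children = fit$control$children,
                  sigma_xi = fit$control$sigma_xi,
                  sigma_eta = fit$control$sigma_eta),
    bounds = list(names = fit$space$names,
                  lower = unname(fit$space$lower),
                  upper = unname(fit$space$upper),
                  scale = unname(fit$space$scale)))
  # 17 significant digits guarantee exact double round-trips
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit back from JSON
#'
#' @param path Path written by [write_fit].
#' @return An `"llv_fit"` object.
#' @export
read_fit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- o$params
  params <- llv_params(a = p$a, b = p$b, x0 = p$x0, c = p$c, d = p$d,
                       y0 = p$y0, e = p$e)
  data <- timeseries_from_frame(as.data.frame(o$data), path)
  structure(list(params = params, free = o$free, loss = o$loss,
                 fitness = o$fitness, history = o$history,
                 evaluations = o$evaluations, seed = o$seed,
                 data = data, step = o$step, model = o$model,
                 space = llv_search_space(o$bounds$names, o$bounds$lower,
                                          o$bounds$upper,
                                          unique(o$bounds$scale)),
                 control = ga_control(o$config$population,
                                      o$config$generations,
                                      o$config$children,
                                      o$config$sigma_xi,
                                      o$config$sigma_eta,
                                      seed = o$seed),
                 call = NULL),
            class = "llv_fit")
}

#' Read a run configuration from YAML
#'
#' A run configuration bundles everything a reproducible run needs:
#' integration settings (`step`, `window`), GA settings (`population`,
#' `generations`, `children`, `sigma_xi`, `sigma_eta`), noise settings
#' (`cv`, `replicates`) and the `seed`.  Missing fields fall back to the
#' package defaults.
#'
#' @param path Path to a YAML file (may be `NULL` for pure defaults).
#' @return A list of class `"llv_run_config"`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(step = 0.01, window = c(0, 92.7),
                   population = 100, generations = 200, children = 50,
                   sigma_xi = 0.5, sigma_eta = 0.35,
                   cv = 0.05, replicates = 4, seed = 1)
  cfg <- if (is.null(path)) defaults
         else modifyList(defaults, yaml::read_yaml(path))
  class(cfg) <- "llv_run_config"
  cfg
}

#' Write the correlation report to CSV
#'
#' @param report An `"llv_correlation"` from [profile_correlations].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(report, path) {
  stopifnot(inherits(report, "llv_correlation"))
  m <- as.data.frame(report$matrix)
  write.csv(cbind(measure = report$labels, m), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
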