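#' Observed cell-population time series
#'
#' The unit of data the model is fitted to: strictly increasing
#' observation times (hr) with positive mean ATP-luminescence intensities,
#' optionally carrying the raw replicate measurements (the mean of the
#' replicates is used for fitting, matching the four-replicate design of
#' the assay).
#'
#' @param times Observation times (hr), strictly increasing and positive.
#' @param values Mean intensity per time (must be positive: the fitting
#'   loss divides by the observations).  May be omitted when `replicates`
#'   is given, in which case row means are used.
#' @param replicates Optional numeric matrix, one row per time and one
#'   column per replicate.
#' @return An object of class `"llv_timeseries"`.
#' @export
llv_timeseries <- function(times, values = NULL, replicates = NULL) {
  times <- as.numeric(times)
  if (length(times) == 0L) stop("time series must not be empty")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    if (nrow(replicates) != length(times))
      stop("replicates must have one row per observation time")
    if (any(!is.finite(replicates)) || any(replicates <= 0))
      stop("replicate intensities must be finite and positive")
    rmeans <- unname(rowMeans(replicates))
    if (is.null(values)) {
      values <- rmeans
    } else if (!isTRUE(all.equal(as.numeric(values), rmeans,
                                 tolerance = 1e-8))) {
      stop("values must equal the mean of the replicates")
    }
  }
  if (is.null(values)) stop("either values or replicates must be supplied")
  values <- as.numeric(values)
  if (length(values) != length(times))
    stop("values and times must have equal length")
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("observation ", bad[1L], " (t = ", times[bad[1L]],
         " hr) is not a positive finite intensity")
  structure(list(times = times, values = values, replicates = replicates),
            class = "llv_timeseries")
}

#' @export
print.llv_timeseries <- function(x, ...) {
  cat(sprintf("Cell-population time series: %d points over [%g, %g] hr%s\n",
              length(x$times), min(x$times), max(x$times),
              if (is.null(x$replicates)) ""
              else sprintf(" (%d replicates)", ncol(x$replicates))))
  print(data.frame(time_hr = x$times, mean = x$values), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.llv_timeseries <- function(x, ...) {
  out <- data.frame(time_hr = x$times)
  if (!is.null(x$replicates)) {
    reps <- as.data.frame(x$replicates)
    names(reps) <- paste0("rep", seq_len(ncol(reps)))
    out <- cbind(out, reps)
  }
  out$mean <- x$values
  out
}

#' Sum of squared relative errors
#'
#' The fitting loss: \eqn{\sum_i ((pred_i - obs_i)/obs_i)^2}.  The
#' relative error divides by the observation, so the loss is invariant
#' under common rescaling of data and prediction but not under additive
#' shifts.  Any non-finite prediction yields `Inf`.
#'
#' @param observed An [llv_timeseries] or a positive numeric vector.
#' @param predicted Numeric vector of model values, same length.
#' @return The loss (non-negative scalar, possibly `Inf`).
#' @examples
#' relative_error_loss(c(100, 200), c(110, 180))  # 0.1^2 + 0.1^2
#' @export
relative_error_loss <- function(observed, predicted) {
  obs <- if (inherits(observed, "llv_timeseries")) observed$values
         else as.numeric(observed)
  if (length(obs) != length(predicted))
    stop("observed and predicted lengths differ")
  if (any(obs <= 0)) stop("observations must be positive")
  if (any(!is.finite(predicted))) return(Inf)
  r <- (predicted - obs) / obs
  sum(r * r)
}

#' Evaluate model fitness against observed data
#'
#' Integrates the model from t = 0 to the last observation time, samples
#' the cell-population curve at the observation times, and returns the
#' squared-relative-error loss together with its reciprocal, the fitness
#' maximised by the genetic algorithm.  A failed integration is reported
#' as `valid = FALSE` with fitness 0 (loss `Inf`); a perfect fit has
#' fitness `Inf`.  Deterministic for fixed inputs.
#'
#' @param params An [llv_params] object.
#' @param observed An [llv_timeseries].
#' @param step RK4 step size (hr).
#' @return A list of class `"llv_fitness"` with elements `loss`,
#'   `fitness` and `valid`.
#' @export
llv_evaluate <- function(params, observed, step = 0.01) {
  stopifnot(inherits(observed, "llv_timeseries"))
  params <- as_llv_params(params)
  traj <- llv_integrate(params, 0, max(observed$times), step)
  loss <- if (!traj$valid) Inf else {
    pred <- sample_at(traj, observed$times)
    relative_error_loss(observed, pred)
  }
  structure(list(loss = loss,
                 fitness = if (!is.finite(loss)) 0
                           else if (loss == 0) Inf else 1 / loss,
                 valid = is.finite(loss)),
            class = "llv_fitness")
}

#' @export
print.llv_fitness <- function(x, ...) {
  cat(sprintf("loss = %.6g, fitness = %.6g%s\n", x$loss, x$fitness,
              if (x$valid) "" else " (invalid trajectory)"))
  invisible(x)
}
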