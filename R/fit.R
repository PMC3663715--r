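#' Fit the prey-predator apoptosis model to a cell-population time course
#'
#' The single fitting front-end.  Two fits make up the study design:
#'
#' * `model = "growth"`: the negative-control fit.  The hidden predator
#'   is absent (`y0 = 0`), the system reduces to logistic growth, and the
#'   three free quantities are `(a, b, x0)`.
#' * `model = "apoptosis"`: a positive-control fit for one siRNA.  The
#'   growth parameters `(a, b, x0)` (and `e`) are held at the values
#'   estimated from the negative control, and the three free quantities
#'   are `(c, d, y0)`.
#'
#' Fitness is the reciprocal of the summed squared relative error between
#' the observed intensities and the model's cell-population curve at the
#' observation times, maximised by the UNDX/MGG real-coded genetic
#' algorithm ([rcga_optimize]).  All randomness flows through one seeded
#' RNG, so a fit is exactly reproducible from its seed.
#'
#' @param data An [llv_timeseries] (or a data frame accepted by
#'   [read_timeseries]'s conventions: columns `time_hr` and `mean` or
#'   `rep*`).
#' @param model `"growth"` or `"apoptosis"`.
#' @param growth For `model = "apoptosis"`: the growth parameters, as a
#'   fitted `"llv_fit"` object or an [llv_params].
#' @param space Optional [llv_search_space]; defaults to the standard
#'   bounds for the three free parameters of the chosen model.
#' @param control A [ga_control]; its `seed` (or the `seed` argument)
#'   makes the fit reproducible.
#' @param step RK4 step size (hr) used inside the objective.
#' @param seed Convenience override for `control$seed`.
#' @return An object of class `"llv_fit"` with components `params` (full
#'   [llv_params] at the optimum), `free` (names of estimated
#'   parameters), `loss`, `fitness`, `history`, `evaluations`, `seed`,
#'   `data`, `step`, `model` and `call`.  Supports `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `simulate` and `plot`.
#' @examples
#' \donttest{
#' neg <- llv_params(a = 3.949e-2, b = 1.445e-8, x0 = 6.512e5)
#' obs <- synthesize_timeseries(neg, noise = noise_model(cv = 0))
#' fit <- llv_fit(obs, "growth", control = ga_control(population = 40,
#'                generations = 40, children = 20, seed = 1), step = 0.1)
#' coef(fit)
#' }
#' @export
llv_fit <- function(data, model = c("growth", "apoptosis"), growth = NULL,
                    space = NULL, control = ga_control(), step = 0.01,
                    seed = NULL) {
  model <- match.arg(model)
  if (!inherits(data, "llv_timeseries")) data <- as_llv_timeseries(data)
  if (!is.null(seed)) control$seed <- seed

  if (model == "growth") {
    free <- c("a", "b", "x0")
    # template: placeholder growth values, no apoptotic arm
    fixed <- llv_params(a = 1e-2, b = 1e-8, x0 = 1e5)
  } else {
    if (is.null(growth))
      stop("an apoptosis fit needs the negative-control growth parameters")
    gp <- as_llv_params(growth)
    free <- c("c", "d", "y0")
    fixed <- llv_params(a = gp$a, b = gp$b, x0 = gp$x0, e = gp$e)
  }
  if (is.null(space)) space <- llv_search_space(free)
  if (!identical(sort(space$names), sort(free)))
    stop("search space must cover exactly (", paste(free, collapse = ", "), ")")

  obj <- model_objective(data, fixed, free, step = step)
  ga <- rcga_optimize(obj, space, control)

  full <- par_vector(fixed)
  full[par_slots[space$names]] <- ga$par
  params <- llv_params(a = full[1L], b = full[2L], e = full[3L],
                       c = full[4L], d = full[5L], x0 = full[6L],
                       y0 = full[7L])
  structure(list(params = params, free = free, loss = ga$loss,
                 fitness = ga$fitness, history = ga$history,
                 evaluations = ga$evaluations, seed = ga$seed,
                 data = data, step = step, model = model,
                 space = space, control = control, call = match.call()),
            class = "llv_fit")
}

as_llv_timeseries <- function(x) {
  if (inherits(x, "llv_timeseries")) return(x)
  if (is.data.frame(x)) return(timeseries_from_frame(x, "data"))
  stop("cannot interpret object of class '", class(x)[1L],
       "' as a time series")
}

#' @export
print.llv_fit <- function(x, ...) {
  cat(sprintf("Prey-predator model fit (%s): loss %.6g, fitness %.6g\n",
              x$model, x$loss, x$fitness))
  print(coef(x))
  invisible(x)
}

#' @export
summary.llv_fit <- function(object, ...) {
  p <- object$params
  structure(list(fit = object,
                 capacity = p$a / p$b,
                 coexistence = if (p$c > 0 && p$a * p$c > p$b * p$d)
                   c(x = p$d / p$c, y = (p$a - p$b * p$d / p$c) / p$e)
                 else NULL,
                 score = if (object$model == "apoptosis") p$c else 0),
            class = "summary.llv_fit")
}

#' @export
print.summary.llv_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Prey-predator apoptosis model, %s fit\n", f$model))
  cat(sprintf("  %d observations over [%g, %g] hr; RK4 step %g hr\n",
              length(f$data$times), min(f$data$times), max(f$data$times),
              f$step))
  cat(sprintf("  GA: %d individuals, %d generations, %g evaluations, seed %d\n",
              f$control$population, f$control$generations, f$evaluations,
              f$seed))
  cat("Estimated parameters:\n")
  print(signif(coef(f), 6))
  cat(sprintf("Loss (sum sq. rel. error): %.6g  (fitness %.6g)\n",
              f$loss, f$fitness))
  cat(sprintf("Carrying capacity a/b: %.6g intensity units\n", x$capacity))
  if (!is.null(x$coexistence))
    cat(sprintf("Coexistence equilibrium: x* = %.6g, y* = %.6g\n",
                x$coexistence["x"], x$coexistence["y"]))
  if (f$model == "apoptosis")
    cat(sprintf("Phenotypic score (c): %.6g\n", x$score))
  invisible(x)
}

#' @export
coef.llv_fit <- function(object, full = FALSE, ...) {
  v <- setNames(par_vector(object$params), names(par_slots))
  if (full) v else v[object$free]
}

#' Predict the model curve of a fitted object
#'
#' Integrates the fitted model from t = 0 and samples the requested
#' component at the requested times.
#'
#' @param object An `"llv_fit"`.
#' @param times Times (hr); defaults to the observation times of the
#'   fitted data.
#' @param component `"x"` (cell population) or `"y"` (hidden siRNA
#'   strength).
#' @param step RK4 step size; defaults to the step used in fitting.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.llv_fit <- function(object, times = object$data$times,
                            component = c("x", "y"), step = object$step,
                            ...) {
  component <- match.arg(component)
  traj <- llv_integrate(object$params, 0, max(times), step)
  if (!traj$valid) stop("fitted model could not be integrated to ",
                        max(times), " hr")
  sample_at(traj, times, component)
}

#' @export
fitted.llv_fit <- function(object, ...) {
  predict(object)
}

#' @export
residuals.llv_fit <- function(object, type = c("relative", "raw"), ...) {
  type <- match.arg(type)
  r <- fitted(object) - object$data$values
  if (type == "relative") r / object$data$values else r
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new synthetic time courses from the fitted parameters under the
#' multiplicative lognormal noise model, mirroring the assay's replicate
#' design.
#'
#' @param object An `"llv_fit"`.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param noise A [noise_model].
#' @param times Sampling times; defaults to the fitted data's times.
#' @param ... Unused.
#' @return A list of `nsim` [llv_timeseries] objects.
#' @export
simulate.llv_fit <- function(object, nsim = 1, seed = NULL,
                             noise = noise_model(),
                             times = object$data$times, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    synthesize_timeseries(object$params, times = times, noise = noise,
                          step = object$step))
}

#' Plot a fitted model over its data
#'
#' Observed mean intensities (points), the fitted cell-population curve
#' (dashed), and, for apoptosis fits, the reconstructed hidden siRNA
#' strength (dotted, secondary axis).
#'
#' @param x An `"llv_fit"`.
#' @param step Integration step for the display curve.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.llv_fit <- function(x, step = x$step, ...) {
  tmax <- max(x$data$times)
  traj <- llv_integrate(x$params, 0, tmax, step)
  op <- par(mar = c(5, 4, 2, 4))
  on.exit(par(op))
  plot(x$data$times, x$data$values, xlab = "time (hr)",
       ylab = "cell population (intensity)",
       ylim = range(0, x$data$values, traj$x), ...)
  lines(traj$times, traj$x, lty = 2)
  if (any(traj$y > 0)) {
    ymax <- max(traj$y)
    lines(traj$times, traj$y / ymax * max(traj$x), lty = 3)
    axis(4, at = c(0, 0.5, 1) * max(traj$x),
         labels = signif(c(0, 0.5, 1) * ymax, 3))
    mtext("siRNA strength", side = 4, line = 2.5)
  }
  invisible(x)
}
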