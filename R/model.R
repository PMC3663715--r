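#' Right-hand side of the prey-predator apoptosis model
#'
#' Evaluates \eqn{dx/dt = x (a - b x - e y)} and
#' \eqn{dy/dt = y (c x - d)} at a single state.  Pure arithmetic:
#' non-finite inputs propagate to non-finite outputs.
#'
#' @param state Numeric vector `c(x, y)`: cell population and siRNA
#'   strength.
#' @param params An [llv_params] object.
#' @return Numeric vector `c(dx, dy)`.
#' @examples
#' p <- llv_params(a = 0.04, b = 1e-8, x0 = 1e5, c = 1e-7, d = 0.1, y0 = 1e-3)
#' llv_rhs(c(0, 0), p)          # extinction fixed point
#' llv_rhs(c(p$d / p$c, (p$a - p$b * p$d / p$c) / p$e), p) # coexistence
#' @export
llv_rhs <- function(state, params) {
  x <- state[[1L]]
  y <- state[[2L]]
  c(x * (params$a - params$b * x - params$e * y),
    y * (params$c * x - params$d))
}

#' Right-hand side of the logistic growth reduction
#'
#' The negative-control model \eqn{dx/dt = x (a - b x)}; identical to the
#' first component of [llv_rhs] with `y = 0`.
#'
#' @param x Cell population.
#' @param a Self-reproduction rate (1/hr).
#' @param b Carrying-capacity coefficient.
#' @return `dx/dt`.
#' @export
logistic_rhs <- function(x, a, b) {
  x * (a - b * x)
}

#' Closed-form logistic growth curve
#'
#' Analytic solution of \eqn{dx/dt = x (a - b x)} with \eqn{x(0) = x_0},
#' used as the exact oracle for the numerical integrator:
#' \deqn{x(t) = \frac{a/b}{1 + (a/(b x_0) - 1) e^{-a t}}.}
#'
#' @param t Time (hr); vectorised.
#' @inheritParams logistic_rhs
#' @param x0 Initial population; must be positive.
#' @return Population at `t`.
#' @export
logistic_closed_form <- function(t, a, b, x0) {
  if (!is.numeric(x0) || any(x0 <= 0)) stop("x0 must be positive")
  if (b <= 0) stop("b must be positive")
  (a / b) / (1 + (a / (b * x0) - 1) * exp(-a * t))
}

#' Integrate the model with fixed-step fourth-order Runge-Kutta
#'
#' Classic RK4 on a uniform grid; the final step is shortened so the grid
#' ends exactly at `t_end`.  If the state ever becomes non-finite, the
#' population non-positive, or the strength negative, integration stops
#' and the trajectory is returned flagged invalid (`valid = FALSE`) with
#' only the valid prefix stored.  Failures are data, not errors, because
#' the genetic algorithm must evaluate arbitrary parameter vectors.
#'
#' @param params An [llv_params] object.
#' @param t_start,t_end Integration window (hr); `t_end > t_start`.
#' @param step RK4 step size (hr), default 0.01.
#' @return An object of class `"llv_trajectory"`; see [llv_trajectory].
#' @examples
#' neg <- llv_params(a = 3.949e-2, b = 1.445e-8, x0 = 6.512e5)
#' traj <- llv_integrate(neg, t_end = 92.7)
#' max(abs(traj$x - logistic_closed_form(traj$times, neg$a, neg$b, neg$x0)) /
#'     traj$x)
#' @export
llv_integrate <- function(params, t_start = 0, t_end, step = 0.01) {
  params <- as_llv_params(params)
  res <- cpp_rk4(par_vector(params), t_start, t_end, step)
  llv_trajectory(times = res$times, x = res$x, y = res$y, step = step,
                 valid = res$valid, t_fail = res$t_fail)
}

#' Trajectory container
#'
#' A dense numerical solution of the model: a time grid together with the
#' cell population `x` and the hidden siRNA strength `y` at every grid
#' point.  Usually produced by [llv_integrate]; the constructor is
#' exported so synthetic trajectories can be built directly (e.g. in
#' quadrature tests).
#'
#' @param times Strictly increasing time grid (hr).
#' @param x,y Component values per grid point.
#' @param step Nominal step size of the grid (hr).
#' @param valid Logical flag; `FALSE` marks a trajectory whose
#'   integration failed part-way.
#' @param t_fail Time at which integration failed (`NA` if it did not).
#' @return An object of class `"llv_trajectory"`.
#' @export
llv_trajectory <- function(times, x, y, step, valid = TRUE, t_fail = NA_real_) {
  times <- as.numeric(times)
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("trajectory times must be strictly increasing")
  if (length(x) != length(times) || length(y) != length(times))
    stop("x and y must match the time grid in length")
  structure(list(times = times, x = as.numeric(x), y = as.numeric(y),
                 step = step, valid = isTRUE(valid), t_fail = t_fail),
            class = "llv_trajectory")
}

#' @export
print.llv_trajectory <- function(x, ...) {
  cat(sprintf("Model trajectory: %d points over [%g, %g] hr (step %g)%s\n",
              length(x$times), x$times[1L], x$times[length(x$times)], x$step,
              if (x$valid) "" else sprintf(" [INVALID at t = %g]", x$t_fail)))
  cat(sprintf("  x in [%.4g, %.4g], y in [%.4g, %.4g]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
as.data.frame.llv_trajectory <- function(x, ...) {
  data.frame(time_hr = x$times, x = x$x, y = x$y)
}

#' Plot a model trajectory
#'
#' Cell population on the left axis, hidden siRNA strength (dotted) on a
#' secondary right axis, the style in which fitted apoptosis curves are
#' conventionally displayed.
#'
#' @param x An `"llv_trajectory"` object.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.llv_trajectory <- function(x, ...) {
  op <- par(mar = c(5, 4, 2, 4))
  on.exit(par(op))
  plot(x$times, x$x, type = "l", xlab = "time (hr)",
       ylab = "cell population (intensity)", ...)
  if (any(x$y > 0)) {
    yr <- range(x$y)
    ys <- if (diff(yr) > 0) (x$y - yr[1L]) / diff(yr) else x$y * 0
    lines(x$times, yr_rescale(ys, x$x), lty = 3)
    axis(4, at = yr_rescale(c(0, 0.5, 1), x$x),
         labels = signif(yr[1L] + c(0, 0.5, 1) * diff(yr), 3))
    mtext("siRNA strength", side = 4, line = 2.5)
  }
  invisible(x)
}

yr_rescale <- function(u, ref) {
  r <- range(ref)
  r[1L] + u * diff(r)
}

#' Sample a trajectory at arbitrary times
#'
#' Linear interpolation between adjacent grid points; requests that hit
#' the grid exactly return the stored values.
#'
#' @param traj An `"llv_trajectory"` object.
#' @param times Times (hr) within the trajectory range.
#' @param component `"x"` (cell population, default) or `"y"` (siRNA
#'   strength).
#' @return Numeric vector of sampled values.
#' @export
sample_at <- function(traj, times, component = c("x", "y")) {
  component <- match.arg(component)
  stopifnot(inherits(traj, "llv_trajectory"))
  cpp_sample(traj$times, traj[[component]], as.numeric(times))
}
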