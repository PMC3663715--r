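#' Parameter set of the prey-predator apoptosis model
#'
#' Bundles the kinetic parameters and initial state of the two-equation
#' model
#' \deqn{dx/dt = x (a - b x - e y), \qquad dy/dt = y (c x - d),}
#' where \eqn{x} is the living-cell population (measured in
#' ATP-luminescence intensity units) and \eqn{y} is the dimensionless
#' apoptotic strength of the transfected siRNA, a hidden state that is
#' never observed directly.
#'
#' The kill coefficient `e` is fixed at 1 by convention: because `y` is
#' dimensionless, the rescaling \eqn{y' = e y} absorbs `e` into
#' \eqn{(c, d, y_0)} without changing the observable \eqn{x}-dynamics, so
#' `e` is not separately identifiable.  It remains settable for
#' experimentation.
#'
#' A negative-control (no active siRNA) parameter set uses
#' `c = d = y0 = 0`, which reduces the system to plain logistic growth
#' with carrying capacity `a/b`.
#'
#' @param a Cell self-reproduction rate (1/hr); must be positive.
#' @param b Carrying-capacity coefficient (1/(hr * intensity unit));
#'   must be positive.  The implied carrying capacity is `a/b`.
#' @param x0 Initial cell population (intensity units); must be positive.
#' @param c siRNA-incorporation coefficient (1/(hr * intensity unit));
#'   non-negative.
#' @param d siRNA-effect decay rate (1/hr); non-negative.
#' @param y0 Initial siRNA strength (dimensionless); non-negative.
#' @param e Apoptotic kill coefficient; defaults to 1 (see Details).
#'
#' @return An object of class `"llv_params"`: a named list with fields
#'   `a`, `b`, `e`, `c`, `d`, `x0`, `y0`.
#' @examples
#' neg <- llv_params(a = 3.949e-2, b = 1.445e-8, x0 = 6.512e5)
#' neg$a / neg$b   # carrying capacity
#' @export
llv_params <- function(a, b, x0, c = 0, d = 0, y0 = 0, e = 1) {
  for (nm in c("a", "b", "x0", "c", "d", "y0", "e")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (a <= 0) stop("a must be positive")
  if (b <= 0) stop("b must be positive")
  if (x0 <= 0) stop("x0 must be positive")
  if (c < 0 || d < 0 || y0 < 0)
    stop("c, d and y0 must be non-negative")
  structure(list(a = a, b = b, e = e, c = c, d = d, x0 = x0, y0 = y0),
            class = "llv_params")
}

# canonical (a,b,e,c,d,x0,y0) ordering used throughout the C++ layer
par_vector <- function(p) {
  c(p$a, p$b, p$e, p$c, p$d, p$x0, p$y0)
}

par_slots <- c(a = 1L, b = 2L, e = 3L, c = 4L, d = 5L, x0 = 6L, y0 = 7L)

as_llv_params <- function(x) {
  if (inherits(x, "llv_params")) return(x)
  if (inherits(x, "llv_fit")) return(x$params)
  if (is.list(x) || (is.numeric(x) && !is.null(names(x)))) {
    x <- as.list(x)
    need <- c("a", "b", "x0")
    if (!all(need %in% names(x)))
      stop("cannot interpret object as model parameters: need a, b, x0")
    return(llv_params(a = x$a, b = x$b, x0 = x$x0,
                      c = if (is.null(x$c)) 0 else x$c,
                      d = if (is.null(x$d)) 0 else x$d,
                      y0 = if (is.null(x$y0)) 0 else x$y0,
                      e = if (is.null(x$e)) 1 else x$e))
  }
  stop("cannot interpret object of class '", class(x)[1L],
       "' as model parameters")
}

#' @export
print.llv_params <- function(x, ...) {
  cat("Prey-predator apoptosis model parameters\n")
  cat(sprintf("  growth:    a = %.4g /hr, b = %.4g, x0 = %.4g (capacity a/b = %.4g)\n",
              x$a, x$b, x$x0, x$a / x$b))
  if (x$c > 0 || x$d > 0 || x$y0 > 0)
    cat(sprintf("  apoptosis: c = %.4g, d = %.4g /hr, y0 = %.4g (e = %g)\n",
                x$c, x$d, x$y0, x$e))
  else
    cat("  apoptosis: none (negative control, y identically 0)\n")
  invisible(x)
}

#' @export
as.numeric.llv_params <- function(x, ...) {
  setNames(par_vector(x), names(par_slots))
}
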