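#' Search space for the genetic algorithm
#'
#' A box of per-parameter bounds, each searched on a linear or log10
#' scale.  The defaults span the plausible ranges of the model's
#' parameters by roughly two decades on either side of typical estimates;
#' because those estimates span seven orders of magnitude, every
#' parameter is searched in log10 by default.
#'
#' @param names Character vector of parameter names, a subset of
#'   `c("a","b","e","c","d","x0","y0")`.
#' @param lower,upper Per-parameter bounds (natural scale).  Defaults are
#'   looked up per name: a in \[1e-3, 1\], b in \[1e-10, 1e-6\],
#'   x0 in \[1e4, 1e7\], c in \[1e-10, 1e-5\], d in \[1e-9, 1\],
#'   y0 in \[1e-6, 1e-1\].
#' @param scale `"log10"` (default) or `"linear"`, recycled per
#'   parameter.  Log-scaled parameters need positive lower bounds.
#' @return An object of class `"llv_search_space"`.
#' @export
llv_search_space <- function(names, lower = NULL, upper = NULL,
                             scale = "log10") {
  defaults <- list(a  = c(1e-3, 1),    b  = c(1e-10, 1e-6),
                   x0 = c(1e4, 1e7),   c  = c(1e-10, 1e-5),
                   d  = c(1e-9, 1),    y0 = c(1e-6, 1e-1))
  n <- length(names)
  if (n < 1L) stop("search space needs at least one parameter")
  if (is.null(lower) || is.null(upper)) {
    if (!all(names %in% names(defaults)))
      stop("no default bounds for: ",
           paste(setdiff(names, names(defaults)), collapse = ", "))
    bd <- vapply(names, function(nm) defaults[[nm]], numeric(2L))
    if (is.null(lower)) lower <- bd[1L, ]
    if (is.null(upper)) upper <- bd[2L, ]
  }
  lower <- setNames(as.numeric(lower), names)
  upper <- setNames(as.numeric(upper), names)
  scale <- setNames(rep_len(match.arg(scale, c("log10", "linear"),
                                      several.ok = FALSE), n), names)
  if (any(lower >= upper)) stop("each lower bound must be below its upper")
  if (any(scale == "log10" & lower <= 0))
    stop("log10-scaled parameters require positive lower bounds")
  structure(list(names = names, lower = lower, upper = upper, scale = scale),
            class = "llv_search_space")
}

space_scaled_bounds <- function(space) {
  lg <- space$scale == "log10"
  list(lower = ifelse(lg, log10(space$lower), space$lower),
       upper = ifelse(lg, log10(space$upper), space$upper),
       logs = as.integer(lg))
}

space_descale <- function(space, v) {
  lg <- space$scale == "log10"
  setNames(ifelse(lg, 10^v, v), space$names)
}

space_rescale <- function(space, v) {
  lg <- space$scale == "log10"
  ifelse(lg, log10(v), v)
}

#' @export
print.llv_search_space <- function(x, ...) {
  cat("GA search space:\n")
  print(data.frame(parameter = x$names, lower = x$lower, upper = x$upper,
                   scale = x$scale), row.names = FALSE)
  invisible(x)
}

#' Genetic-algorithm settings
#'
#' Hyperparameters of the real-coded GA.  One "generation" is defined as
#' `population/2` MGG family events, so the total number of objective
#' evaluations is `population + generations * (population/2) * children`.
#'
#' @param population Population size (at least 3; UNDX needs three
#'   parents).  Default 100.
#' @param generations Number of generations.  Default 200.
#' @param children Children generated per MGG family event (at least 2).
#'   Default 50.
#' @param sigma_xi UNDX spread along the primary (parent1-parent2) axis.
#'   Default 0.5.
#' @param sigma_eta UNDX spread orthogonal to the primary axis, divided
#'   internally by sqrt(n).  Default 0.35.
#' @param seed Optional integer seed; when given, [rcga_optimize] seeds
#'   R's RNG so the run is exactly reproducible.
#' @return An object of class `"llv_ga_control"`.
#' @export
ga_control <- function(population = 100, generations = 200, children = 50,
                       sigma_xi = 0.5, sigma_eta = 0.35, seed = NULL) {
  if (population < 3) stop("population must be at least 3")
  if (children < 2) stop("children must be at least 2")
  if (generations < 1) stop("generations must be at least 1")
  if (sigma_xi <= 0 || sigma_eta <= 0) stop("UNDX spreads must be positive")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 children = as.integer(children),
                 sigma_xi = sigma_xi, sigma_eta = sigma_eta,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "llv_ga_control")
}

#' Unimodal normal distribution crossover (UNDX)
#'
#' Generates one child from three real-vector parents: the child is drawn
#' from a normal distribution centred on the midpoint of parents 1 and 2,
#' spread `sigma_xi` along their difference vector and
#' `sigma_eta/sqrt(n)` (scaled by the distance of parent 3 from that
#' line) in the orthogonal subspace.  Three identical parents reproduce
#' the common point exactly; in one dimension no orthogonal component
#' exists.
#'
#' @param parent1,parent2,parent3 Numeric vectors of equal length.
#' @param sigma_xi,sigma_eta Spread parameters (see [ga_control]).
#' @return A child vector of the same length.
#' @export
undx_crossover <- function(parent1, parent2, parent3,
                           sigma_xi = 0.5, sigma_eta = 0.35) {
  if (length(parent2) != length(parent1) ||
      length(parent3) != length(parent1))
    stop("parents must have equal dimension")
  cpp_undx(as.numeric(parent1), as.numeric(parent2), as.numeric(parent3),
           sigma_xi, sigma_eta)
}

# Wrap a user objective (natural scale, named vector -> loss) for C++.
r_objspec <- function(objective, space) {
  list(type = "r", fun = function(v) {
    l <- objective(v)
    if (!is.numeric(l) || length(l) != 1L) stop("objective must return one number")
    as.numeric(l)
  }, names = space$names)
}

# Native fast path: model loss over a parameter subset.
model_objspec <- function(objective) {
  list(type = "llv", template = objective$template,
       idx = objective$idx - 1L, times = objective$times,
       obs = objective$obs, step = objective$step)
}

#' Model-fitting objective for the genetic algorithm
#'
#' Builds the squared-relative-error loss over a subset of the model
#' parameters, with the remaining parameters held fixed.  [rcga_optimize]
#' recognises this object and evaluates it in compiled code, which is
#' what makes population-scale fitting practical.
#'
#' @param observed An [llv_timeseries].
#' @param fixed An [llv_params] object providing the values of all
#'   parameters not under search.
#' @param free Character vector of searched parameter names.
#' @param step RK4 step size (hr) used inside the loss.
#' @return An object of class `"llv_model_objective"`.  Calling it as a
#'   function on a named parameter vector returns the loss, so it can
#'   also be used directly.
#' @export
model_objective <- function(observed, fixed, free, step = 0.01) {
  stopifnot(inherits(observed, "llv_timeseries"))
  fixed <- as_llv_params(fixed)
  if (!all(free %in% names(par_slots)))
    stop("unknown parameter names: ",
         paste(setdiff(free, names(par_slots)), collapse = ", "))
  obj <- structure(list(template = par_vector(fixed),
                        idx = unname(par_slots[free]), free = free,
                        times = observed$times, obs = observed$values,
                        step = step),
                   class = "llv_model_objective")
  obj
}

model_objective_loss <- function(objective, v) {
  full <- objective$template
  full[objective$idx] <- v[objective$free]
  cpp_llv_loss(full, objective$times, objective$obs, objective$step)
}

#' One MGG family event
#'
#' Minimal generation gap selection: two distinct parents are drawn at
#' random (plus a third for UNDX), `children` UNDX children are generated
#' and evaluated, and the two parent slots are replaced by (i) the
#' family's best individual and (ii) one family member drawn by
#' fitness-proportionate roulette.  All other individuals are untouched,
#' so the population's best loss never increases.
#'
#' @param population Numeric matrix, one individual per row, natural
#'   scale, columns named as in `space`.
#' @param losses Numeric vector of current losses (may be `NULL`, in
#'   which case all individuals are evaluated first).
#' @param objective Function mapping a named natural-scale vector to a
#'   loss, or an object from [model_objective].
#' @param space An [llv_search_space].
#' @param control A [ga_control] object (only `children`, `sigma_xi`,
#'   `sigma_eta` are used).
#' @return A list with the updated `population`, `losses`, and the
#'   number of objective `evaluations` performed.
#' @export
mgg_step <- function(population, losses = NULL, objective, space,
                     control = ga_control()) {
  population <- as.matrix(population)
  sb <- space_scaled_bounds(space)
  scaled <- population
  for (j in seq_along(space$names))
    scaled[, j] <- if (sb$logs[j]) log10(population[, j]) else population[, j]
  spec <- make_objspec(objective, space)
  if (is.null(losses)) {
    losses <- apply(population, 1L, function(v)
      eval_objspec(spec, setNames(v, space$names)))
  }
  res <- cpp_mgg_step(scaled, as.numeric(losses), sb$lower, sb$upper,
                      sb$logs, control$children, control$sigma_xi,
                      control$sigma_eta, spec)
  pop <- res$population
  for (j in seq_along(space$names))
    if (sb$logs[j]) pop[, j] <- 10^pop[, j]
  colnames(pop) <- space$names
  list(population = pop, losses = res$losses, evaluations = res$evaluations)
}

make_objspec <- function(objective, space) {
  if (inherits(objective, "llv_model_objective")) {
    if (!identical(sort(objective$free), sort(space$names)))
      stop("objective searches (", paste(objective$free, collapse = ", "),
           ") but the space defines (", paste(space$names, collapse = ", "), ")")
    # reorder template index to the space's parameter order
    idx <- objective$idx[match(space$names, objective$free)]
    list(type = "llv", template = objective$template, idx = idx - 1L,
         times = objective$times, obs = objective$obs, step = objective$step)
  } else if (is.function(objective)) {
    r_objspec(objective, space)
  } else stop("objective must be a function or a model_objective()")
}

eval_objspec <- function(spec, v) {
  if (identical(spec$type, "r")) spec$fun(v)
  else {
    full <- spec$template
    full[spec$idx + 1L] <- v
    cpp_llv_loss(full, spec$times, spec$obs, spec$step)
  }
}

#' Real-coded genetic algorithm with UNDX and MGG
#'
#' Maximises the reciprocal-loss fitness over a bounded box: the
#' population is initialised uniformly at random in the (scaled) box and
#' `generations * population/2` MGG family events are run.  Out-of-bound
#' children are clipped to the boundary.  Objective failures (non-finite
#' loss) are tolerated as zero-fitness individuals and never raise.
#'
#' @inheritParams mgg_step
#' @param control A [ga_control] object.
#' @return An object of class `"llv_ga_fit"`: a list with `par` (named,
#'   natural scale), `loss`, `fitness`, `history` (best loss per
#'   generation, non-increasing), `evaluations` and `seed`.
#' @examples
#' sp <- llv_search_space(c("u", "v"), lower = c(-5, -5), upper = c(5, 5),
#'                        scale = "linear")
#' f <- function(p) sum((p - c(1, -2))^2)
#' fit <- rcga_optimize(f, sp, ga_control(population = 30, generations = 30,
#'                                        children = 10, seed = 1))
#' fit$par
#' @export
rcga_optimize <- function(objective, space, control = ga_control()) {
  stopifnot(inherits(space, "llv_search_space"),
            inherits(control, "llv_ga_control"))
  seed <- control$seed
  if (is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  set.seed(seed)
  sb <- space_scaled_bounds(space)
  spec <- make_objspec(objective, space)
  res <- cpp_rcga(sb$lower, sb$upper, sb$logs, control$population,
                  control$generations, control$children,
                  control$sigma_xi, control$sigma_eta, spec)
  structure(list(par = setNames(res$par, space$names), loss = res$loss,
                 fitness = if (!is.finite(res$loss)) 0
                           else if (res$loss == 0) Inf else 1 / res$loss,
                 history = res$history, evaluations = res$evaluations,
                 seed = seed, space = space, control = control),
            class = "llv_ga_fit")
}

#' @export
print.llv_ga_fit <- function(x, ...) {
  cat(sprintf("RCGA fit: loss %.6g after %g evaluations (seed %d)\n",
              x$loss, x$evaluations, x$seed))
  print(signif(x$par, 6))
  invisible(x)
}
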