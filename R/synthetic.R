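#' Canonical assay sampling times
#'
#' The ten observation times (hr after the start of cultivation) of the
#' ATP-luminescence viability assay design emulated by the synthetic
#' generator.  siRNA transfection starts together with cultivation, so
#' t = 0 is the initial state and the first observation at 2.4 hr is an
#' interior point.
#'
#' @return Numeric vector of 10 times (hr).
#' @export
assay_times <- function() {
  c(2.4, 5.4, 8.0, 20.7, 29.0, 44.9, 52.7, 68.7, 76.8, 92.7)
}

#' Multiplicative measurement-noise model
#'
#' Luminescence intensities are positive with roughly scale-proportional
#' scatter, so replicates are modelled as the true curve times lognormal
#' factors with median 1 and log-sd \eqn{\sqrt{\ln(1 + cv^2)}}.  The
#' default coefficient of variation of 5% is a plausible replicate
#' scatter for plate-based ATP viability assays; the replicate count of
#' 4 mirrors the assay design.
#'
#' @param cv Coefficient of variation per replicate (>= 0; 0 gives
#'   noiseless data).
#' @param replicates Number of replicates per time point (>= 1).
#' @return An object of class `"llv_noise"`.
#' @export
noise_model <- function(cv = 0.05, replicates = 4) {
  if (cv < 0) stop("cv must be non-negative")
  if (replicates < 1) stop("replicates must be at least 1")
  structure(list(cv = cv, replicates = as.integer(replicates)),
            class = "llv_noise")
}

#' Generate a synthetic cell-population time course
#'
#' Integrates the model, samples the cell-population curve at the given
#' times, and draws `replicates` lognormal noise factors per time point.
#' The returned series stores the replicate values and their mean (the
#' quantity used for fitting).  With `cv = 0` the values equal the model
#' curve exactly.
#'
#' @param params An [llv_params] object.
#' @param times Sampling times (hr), strictly increasing and positive;
#'   default [assay_times()].
#' @param noise A [noise_model].
#' @param step RK4 step (hr).
#' @return An [llv_timeseries] with replicates.
#' @examples
#' neg <- llv_params(a = 3.949e-2, b = 1.445e-8, x0 = 6.512e5)
#' set.seed(1)
#' obs <- synthesize_timeseries(neg)
#' obs
#' @export
synthesize_timeseries <- function(params, times = assay_times(),
                                  noise = noise_model(), step = 0.01) {
  stopifnot(inherits(noise, "llv_noise"))
  params <- as_llv_params(params)
  times <- as.numeric(times)
  if (any(times <= 0) || (length(times) > 1L && any(diff(times) <= 0)))
    stop("times must be positive and strictly increasing")
  traj <- llv_integrate(params, 0, max(times), step)
  if (!traj$valid)
    stop("parameters are not integrable over the sampling window ",
         "(failed at t = ", traj$t_fail, " hr); no data generated")
  xs <- sample_at(traj, times)
  n <- length(times)
  r <- noise$replicates
  factors <- if (noise$cv == 0) {
    matrix(1, n, r)
  } else {
    sdlog <- sqrt(log(1 + noise$cv^2))
    matrix(exp(rnorm(n * r, mean = 0, sd = sdlog)), n, r)
  }
  reps <- xs * factors
  llv_timeseries(times, values = rowMeans(reps), replicates = reps)
}

#' Generate a panel of synthetic time courses
#'
#' One synthetic series per condition of a parameter panel (negative
#' control plus siRNAs, all sharing the growth parameters), as produced
#' by [sirna_panel()].
#'
#' @param panel Named list of [llv_params]; default the packaged
#'   reference panel.
#' @inheritParams synthesize_timeseries
#' @return Named list of [llv_timeseries].
#' @export
synthesize_panel <- function(panel = sirna_panel(), times = assay_times(),
                             noise = noise_model(), step = 0.01) {
  if (is.null(names(panel))) stop("panel must be a named list")
  lapply(panel, synthesize_timeseries, times = times, noise = noise,
         step = step)
}

#' Reference parameter panel for six apoptosis-inducing siRNAs
#'
#' The packaged set of fitted model parameters for six commercial
#' apoptosis-inducing siRNAs in HeLa cells (ACD, KIF, PLK, VHP, HP, MP)
#' together with the negative control: a shared logistic growth model
#' (`a`, `b`, `x0`) and per-siRNA apoptotic parameters (`c`, `d`,
#' `y0`).  Used as the generator fixture for recovery studies and as the
#' input of the correlation / classification analyses.
#'
#' @param file Path to a CSV with columns `name, a, b, x0, c, d, y0`;
#'   default the panel shipped with the package.
#' @return A named list of [llv_params] of class `"llv_panel"`.
#' @export
sirna_panel <- function(file = system.file("extdata", "sirna_params.csv",
                                           package = "llvrnai")) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "a", "b", "x0", "c", "d", "y0")
  if (!all(need %in% names(df)))
    stop("panel file must have columns ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    llv_params(a = df$a[i], b = df$b[i], x0 = df$x0[i],
               c = df$c[i], d = df$d[i], y0 = df$y0[i]))
  names(out) <- df$name
  class(out) <- "llv_panel"
  out
}

#' @export
print.llv_panel <- function(x, ...) {
  cat("siRNA parameter panel:", paste(names(x), collapse = ", "), "\n")
  df <- do.call(rbind, lapply(x, function(p)
    data.frame(a = p$a, b = p$b, x0 = p$x0, c = p$c, d = p$d, y0 = p$y0)))
  print(cbind(name = names(x), df), row.names = FALSE)
  invisible(x)
}

#' @export
`[.llv_panel` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "llv_panel"
  out
}
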