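#' Area under a trajectory component
#'
#' Composite trapezoid quadrature over the stored grid, restricted to a
#' window whose endpoints are linearly interpolated when they fall
#' between grid points.
#'
#' @param traj A valid `"llv_trajectory"`.
#' @param component `"y"` (siRNA strength, default) or `"x"`.
#' @param window Numeric `c(t_lo, t_hi)` inside the trajectory range;
#'   defaults to the full range.
#' @return The area (component units times hours).
#' @export
traj_auc <- function(traj, component = c("y", "x"), window = NULL) {
  component <- match.arg(component)
  g <- window_grid(traj, component, window)
  trapezoid(g$t, g$v)
}

#' Accumulated population difference between two conditions
#'
#' The trapezoid integral of \eqn{x_{neg}(t) - x_{pos}(t)} over a window:
#' the cells lost to apoptosis, accumulated over time.  Positive whenever
#' the siRNA-treated culture stays below the untreated one.
#'
#' @param neg_traj,pos_traj Valid `"llv_trajectory"` objects for the
#'   negative control and the siRNA-treated condition, over the same
#'   range.
#' @inheritParams traj_auc
#' @return The accumulated difference (intensity units times hours).
#' @export
diff_effect <- function(neg_traj, pos_traj, window = NULL) {
  gn <- window_grid(neg_traj, "x", window)
  gp <- window_grid(pos_traj, "x", window)
  if (length(gn$t) != length(gp$t) || max(abs(gn$t - gp$t)) > 1e-9)
    stop("trajectories must share one time grid over the window")
  trapezoid(gn$t, gn$v - gp$v)
}

#' Peak of the hidden siRNA-strength curve
#'
#' Maximum stored `y` within the window (grid maximum, no sub-grid
#' interpolation beyond the window endpoints).
#'
#' @inheritParams traj_auc
#' @return The peak strength.
#' @export
peak_height <- function(traj, window = NULL) {
  g <- window_grid(traj, "y", window)
  if (length(g$t) == 0L) stop("window contains no trajectory points")
  max(g$v)
}

# restrict a trajectory component to [t_lo, t_hi], interpolating endpoints
window_grid <- function(traj, component, window) {
  stopifnot(inherits(traj, "llv_trajectory"))
  if (!traj$valid) stop("trajectory is flagged invalid (failed at t = ",
                        traj$t_fail, ")")
  ts <- traj$times
  vs <- traj[[component]]
  if (is.null(window)) return(list(t = ts, v = vs))
  if (length(window) != 2L || window[1L] > window[2L])
    stop("window must be c(t_lo, t_hi) with t_lo <= t_hi")
  tol <- 1e-9 * max(1, abs(ts[length(ts)]))
  if (window[1L] < ts[1L] - tol || window[2L] > ts[length(ts)] + tol)
    stop("window must lie within the trajectory range")
  if (window[1L] == window[2L]) {
    return(list(t = window[1L], v = cpp_sample(ts, vs, window[1L])))
  }
  inside <- ts > window[1L] + tol & ts < window[2L] - tol
  t_out <- c(window[1L], ts[inside], window[2L])
  v_out <- c(cpp_sample(ts, vs, window[1L]), vs[inside],
             cpp_sample(ts, vs, window[2L]))
  list(t = t_out, v = v_out)
}

trapezoid <- function(t, v) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (head(v, -1L) + tail(v, -1L)) / 2)
}

#' Per-siRNA effect summaries from fitted models
#'
#' For each siRNA, simulates the fitted model and the shared
#' negative-control model over a common window and derives the three
#' effect measures of the analysis:
#'
#' * `diff` - accumulated difference between the negative-control and
#'   treated cell-population curves (intensity * hr);
#' * `sirna_auc` - area under the hidden siRNA-strength curve
#'   (strength * hr);
#' * `height` - peak of the strength curve;
#'
#' together with the fitted `c` and `d` carried through for the
#' correlation analysis.
#'
#' @param fits Named list of apoptosis fits: `"llv_fit"` objects or full
#'   [llv_params].  All are expected to share the negative-control
#'   growth parameters.
#' @param neg The negative-control fit or parameters.
#' @param window Integration window (hr); default `c(0, 92.7)`, the
#'   cultivation start to the last observation.
#' @param step RK4 step (hr), default 0.01.
#' @return A data frame of class `"llv_profiles"` with columns `name`,
#'   `diff`, `sirna_auc`, `height`, `c`, `d`.
#' @examples
#' panel <- sirna_panel()
#' prof <- profile_summaries(panel[names(panel) != "Neg"], panel$Neg)
#' prof
#' @export
profile_summaries <- function(fits, neg, window = c(0, 92.7), step = 0.01) {
  neg_p <- as_llv_params(neg)
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be a named list")
  neg_traj <- llv_integrate(neg_p, 0, window[2L], step)
  if (!neg_traj$valid) stop("negative-control model failed to integrate")
  rows <- lapply(names(fits), function(nm) {
    p <- as_llv_params(fits[[nm]])
    traj <- llv_integrate(p, 0, window[2L], step)
    if (!traj$valid) stop("model '", nm, "' failed to integrate")
    data.frame(name = nm,
               diff = diff_effect(neg_traj, traj, window),
               sirna_auc = traj_auc(traj, "y", window),
               height = peak_height(traj, window),
               c = p$c, d = p$d)
  })
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("llv_profiles", "data.frame")
  out
}

#' Covariance PCA of the (c, d) parameter pairs
#'
#' Principal component analysis of the raw, mean-centred `(c, d)` pairs
#' without variance scaling.  On raw scales `d` is typically orders of
#' magnitude more variable than `c`, so the first component is dominated
#' by `d`; the alternative correlation-scaled PCA (which loads both
#' parameters equally) is available via `scale. = TRUE`.  The loading
#' sign is fixed so that the `d` loading is positive.
#'
#' @param c_values,d_values Numeric vectors (at least 3 points).
#' @param scale. Scale to unit variance before the decomposition?
#'   Default `FALSE` (covariance PCA).
#' @return A list with `scores` (PC1 scores), `loadings` (unit-norm
#'   loading vector on `(c, d)`), `center`, and `sdev`.
#' @export
pca_cd <- function(c_values, d_values, scale. = FALSE) {
  X <- cbind(c = as.numeric(c_values), d = as.numeric(d_values))
  if (nrow(X) < 3L) stop("PCA needs at least 3 points")
  if (all(apply(X, 2L, function(v) max(v) == min(v))))
    stop("degenerate input: all points identical")
  pr <- stats::prcomp(X, center = TRUE, scale. = scale.)
  v <- pr$rotation[, 1L]
  s <- pr$x[, 1L]
  if (v["d"] < 0) { v <- -v; s <- -s }
  list(scores = unname(s), loadings = v, center = pr$center,
       sdev = pr$sdev)
}

#' Correlation report over the effect measures
#'
#' Pairwise Pearson correlations among the six quantities of the profile
#' analysis, in the conventional order `Diff.`, `siRNA` (area under the
#' strength curve), `height`, `c`, `d`, `PC1` (first-component scores of
#' the (c, d) PCA).  A zero-variance column makes its correlations
#' undefined; these are flagged `NA` with a warning rather than silently
#' propagated.
#'
#' @param profiles An `"llv_profiles"` data frame from
#'   [profile_summaries] (at least 3 siRNAs).
#' @param pca `"covariance"` (default) or `"correlation"`: scaling used
#'   for the PC1 scores.
#' @return An object of class `"llv_correlation"`: list with `labels`,
#'   `matrix` (symmetric, unit diagonal), `pc1_scores`, `pc1_loadings`.
#' @export
profile_correlations <- function(profiles, pca = c("covariance",
                                                   "correlation")) {
  pca <- match.arg(pca)
  stopifnot(inherits(profiles, "data.frame"))
  if (nrow(profiles) < 3L) stop("correlation analysis needs >= 3 siRNAs")
  pc <- pca_cd(profiles$c, profiles$d, scale. = (pca == "correlation"))
  M <- cbind(Diff. = profiles$diff, siRNA = profiles$sirna_auc,
             height = profiles$height, c = profiles$c, d = profiles$d,
             PC1 = pc$scores)
  sds <- apply(M, 2L, sd)
  R <- suppressWarnings(cor(M))
  if (any(sds == 0)) {
    warning("zero-variance measure(s): ",
            paste(colnames(M)[sds == 0], collapse = ", "),
            "; their correlations are undefined (NA)")
    R[sds == 0, ] <- NA_real_
    R[, sds == 0] <- NA_real_
  }
  diag(R) <- 1
  structure(list(labels = colnames(M), matrix = R,
                 pc1_scores = setNames(pc$scores, profiles$name),
                 pc1_loadings = pc$loadings, pca = pca),
            class = "llv_correlation")
}

#' @export
print.llv_correlation <- function(x, digits = 5, ...) {
  cat("Pearson correlations between siRNA effect measures\n")
  cat(sprintf("(PC1 from %s-scaled PCA of the raw (c, d) pairs)\n", x$pca))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Classify siRNAs into strong- and weak-effect groups
#'
#' Deterministic 2-means clustering of the standardised
#' `(log10 c, log10 d)` pairs: the two points farthest apart in that
#' plane seed the clusters (Lloyd iterations), and the cluster with the
#' larger mean `log10 d` is labelled `"strong"`.  A hard threshold is
#' deliberately avoided so the rule generalises beyond any particular
#' panel.  If all points coincide the grouping is degenerate: everything
#' is labelled `"strong"` with a warning.
#'
#' @param x An `"llv_profiles"` data frame, or any data frame / matrix
#'   with positive columns `c` and `d` (at least 2 rows).
#' @return A factor with levels `c("strong", "weak")`, named by siRNA
#'   where names are available.
#' @examples
#' panel <- sirna_panel()
#' prof <- profile_summaries(panel[names(panel) != "Neg"], panel$Neg,
#'                           step = 0.1)
#' classify_strength(prof)
#' @export
classify_strength <- function(x) {
  df <- as.data.frame(x)
  if (!all(c("c", "d") %in% names(df)))
    stop("need columns 'c' and 'd'")
  if (nrow(df) < 2L) stop("classification needs at least 2 points")
  if (any(df$c <= 0 | df$d <= 0))
    stop("classification requires positive c and d (apoptosis fits only)")
  nm <- if ("name" %in% names(df)) df$name else rownames(df)
  Z <- cbind(log10(df$c), log10(df$d))
  Z <- apply(Z, 2L, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  D <- as.matrix(dist(Z))
  if (max(D) == 0) {
    warning("all points coincide; strong/weak grouping is degenerate")
    return(setNames(factor(rep("strong", nrow(df)),
                           levels = c("strong", "weak")), nm))
  }
  far <- which(D == max(D), arr.ind = TRUE)[1L, ]
  km <- stats::kmeans(Z, centers = Z[c(far[1L], far[2L]), , drop = FALSE],
                      algorithm = "Lloyd", iter.max = 100L)
  mean_logd <- tapply(log10(df$d), km$cluster, mean)
  strong_id <- as.integer(names(mean_logd)[which.max(mean_logd)])
  setNames(factor(ifelse(km$cluster == strong_id, "strong", "weak"),
                  levels = c("strong", "weak")), nm)
}

#' Phenotypic score of an siRNA
#'
#' The fitted siRNA-incorporation coefficient `c`, proposed as a
#' sequence-free score of apoptotic effectiveness: larger `c`, stronger
#' effect.  The fit's loss is attached as a quality annotation.  A
#' growth (negative-control) fit has no apoptotic arm and scores 0.
#'
#' @param fit An `"llv_fit"` or an [llv_params].
#' @return The score (numeric scalar) with attribute `"loss"` when
#'   available.
#' @export
phenotypic_score <- function(fit) {
  if (inherits(fit, "llv_fit")) {
    if (fit$model != "apoptosis") return(0)
    structure(fit$params$c, loss = fit$loss)
  } else {
    as_llv_params(fit)$c
  }
}

#' Scatter plot of the (c, d) parameter plane
#'
#' log10-log10 scatter of the fitted `(c, d)` pairs, labelled by siRNA
#' and coloured by the strong/weak grouping.
#'
#' @param x An `"llv_profiles"` data frame.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.llv_profiles <- function(x, ...) {
  grp <- classify_strength(x)
  plot(log10(x$c), log10(x$d), pch = ifelse(grp == "strong", 19, 1),
       xlab = "log10 c (incorporation)", ylab = "log10 d (decay)", ...)
  text(log10(x$c), log10(x$d), labels = x$name, pos = 3, cex = 0.8)
  legend("bottomright", pch = c(19, 1), legend = c("strong", "weak"))
  invisible(x)
}
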