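test_that("model right-hand side vanishes at its fixed points", {
  p <- sirna_pars("ACD")
  # extinction
  expect_identical(llv_rhs(c(0, 0), p), c(0, 0))
  # coexistence equilibrium (a*c > b*d holds for ACD)
  xeq <- p$d / p$c
  yeq <- (p$a - p$b * xeq) / p$e
  expect_true(p$a * p$c > p$b * p$d)
  deriv <- llv_rhs(c(xeq, yeq), p)
  expect_lt(abs(deriv[1L]) / (p$a * xeq), 1e-12)
  expect_lt(abs(deriv[2L]) / (p$d * yeq), 1e-12)
  # carrying capacity of the predator-free system
  g <- neg_pars()
  K <- g$a / g$b
  expect_equal(K, 2732871.97, tolerance = 1e-6)
  expect_equal(llv_rhs(c(K, 0), g), c(0, 0), tolerance = 1e-20)
})

test_that("logistic reduction is exact and has the textbook shape", {
  g <- neg_pars()
  expect_identical(logistic_rhs(0, g$a, g$b), 0)
  expect_equal(logistic_rhs(g$a / g$b, g$a, g$b), 0, tolerance = 1e-18)
  # vertex: maximal growth at half capacity
  expect_equal(logistic_rhs(g$a / (2 * g$b), g$a, g$b),
               g$a^2 / (4 * g$b))
  # e*y0 = 0 reduces the x-equation bitwise
  xs <- c(1, 1e3, 6.512e5, 2.7e6)
  for (x in xs)
    expect_identical(llv_rhs(c(x, 0), g)[1L], logistic_rhs(x, g$a, g$b))
  # non-finite inputs propagate
  expect_true(is.nan(llv_rhs(c(NaN, 0), g)[1L]))
})

test_that("closed-form logistic curve satisfies its boundary behaviour", {
  g <- neg_pars()
  expect_identical(logistic_closed_form(0, g$a, g$b, g$x0), g$x0)
  expect_equal(logistic_closed_form(50 / g$a, g$a, g$b, g$x0), g$a / g$b,
               tolerance = 1e-12)
  # frozen regression value at the last observation time
  expect_equal(logistic_closed_form(92.7, g$a, g$b, g$x0),
               2525295.419546, tolerance = 1e-10)
  expect_error(logistic_closed_form(1, g$a, g$b, -1), "positive")
})

test_that("RK4 reproduces the analytic logistic curve", {
  g <- neg_pars()
  traj <- llv_integrate(g, 0, 92.7, step = 0.01)
  expect_true(traj$valid)
  expect_identical(traj$y, rep(0, length(traj$times)))
  cf <- logistic_closed_form(traj$times, g$a, g$b, g$x0)
  expect_lt(max(abs(traj$x - cf) / cf), 1e-8)
  # grid endpoints stored exactly, partial final step lands on t_end
  traj2 <- llv_integrate(g, 0, 92.705, step = 0.01)
  expect_identical(traj2$times[1L], 0)
  expect_identical(traj2$times[length(traj2$times)], 92.705)
})

test_that("RK4 converges at fourth order where truncation dominates", {
  g <- neg_pars()
  steps <- c(0.64, 0.32, 0.16, 0.08)
  errs <- vapply(steps, function(h) {
    tr <- llv_integrate(g, 0, 92.7, h)
    cf <- logistic_closed_form(tr$times, g$a, g$b, g$x0)
    max(abs(tr$x - cf) / cf)
  }, numeric(1L))
  slope <- coef(lm(log(errs) ~ log(steps)))[[2L]]
  expect_gt(slope, 3.7)
  expect_lt(slope, 4.3)
})

test_that("RK4 agrees with an independent integrator on the full system", {
  skip_if_not_installed("deSolve")
  p <- sirna_pars("KIF")
  tg <- seq(0, 92.7, by = 0.01)
  rhs <- function(t, s, q) list(c(s[1] * (p$a - p$b * s[1] - p$e * s[2]),
                                  s[2] * (p$c * s[1] - p$d)))
  ref <- deSolve::rk4(c(p$x0, p$y0), tg, rhs, NULL)
  traj <- llv_integrate(p, 0, 92.7, 0.01)
  expect_equal(traj$x, unname(ref[, 2L]), tolerance = 1e-10)
  expect_equal(traj$y, unname(ref[, 3L]), tolerance = 1e-10)
})

test_that("a trajectory started at the coexistence equilibrium stays there", {
  p <- sirna_pars("ACD")
  xeq <- p$d / p$c
  yeq <- (p$a - p$b * xeq) / p$e
  eq <- llv_params(a = p$a, b = p$b, x0 = xeq, c = p$c, d = p$d, y0 = yeq)
  tr <- llv_integrate(eq, 0, 100, 0.01)
  expect_lt(max(abs(tr$x - xeq) / xeq), 1e-10)
  expect_lt(max(abs(tr$y - yeq) / yeq), 1e-10)
})

test_that("long integrations orbit the coexistence equilibrium", {
  p <- sirna_pars("ACD")
  tr <- llv_integrate(p, 0, 400, 0.01)
  crossings <- sum(diff(sign(tr$x - p$d / p$c)) != 0)
  expect_gte(crossings, 2L)
})

test_that("integration failures are flagged, never raised", {
  boom <- llv_params(a = 1e6, b = 1e-8, x0 = 1e5)
  tr <- llv_integrate(boom, 0, 92.7, 0.01)
  expect_false(tr$valid)
  expect_true(is.finite(tr$t_fail))
  # the stored prefix is still physical
  expect_true(all(tr$x > 0))
})

test_that("trajectory sampling interpolates linearly and checks its range", {
  g <- neg_pars()
  tr <- llv_integrate(g, 0, 92.7, 0.01)
  # exact grid hit returns the stored value
  expect_identical(sample_at(tr, tr$times[101L]), tr$x[101L])
  # midpoint of a segment returns the mean of its ends
  tm <- (tr$times[5L] + tr$times[6L]) / 2
  expect_equal(sample_at(tr, tm), (tr$x[5L] + tr$x[6L]) / 2)
  expect_error(sample_at(tr, 100), "outside")
  # the ten assay times give finite positive populations
  v <- sample_at(tr, assay_times())
  expect_true(all(is.finite(v) & v > 0))
  expect_equal(v, logistic_closed_form(assay_times(), g$a, g$b, g$x0),
               tolerance = 1e-9)
})
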