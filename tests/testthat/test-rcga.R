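test_that("UNDX reproduces identical parents exactly and is unbiased", {
  p <- c(1.5, -2, 1e-3)
  set.seed(1)
  expect_identical(undx_crossover(p, p, p), p)
  # one-dimensional search has no orthogonal component: the child stream
  # is unchanged by sigma_eta
  set.seed(7)
  a1 <- replicate(50, undx_crossover(0, 1, 5, sigma_eta = 0.35))
  set.seed(7)
  a2 <- replicate(50, undx_crossover(0, 1, 5, sigma_eta = 1000))
  expect_identical(a1, a2)
  # Monte-Carlo unbiasedness: children centre on the parents' midpoint
  p1 <- c(0, 0, 0); p2 <- c(2, 1, -1); p3 <- c(1, 3, 2)
  set.seed(11)
  kids <- t(replicate(10000, undx_crossover(p1, p2, p3)))
  mid <- (p1 + p2) / 2
  se <- apply(kids, 2L, sd) / sqrt(nrow(kids))
  expect_true(all(abs(colMeans(kids) - mid) < 3 * se))
  expect_error(undx_crossover(c(1, 2), c(1, 2, 3), c(1, 2)), "dimension")
})

test_that("an MGG family event preserves the population's best loss", {
  sp <- llv_search_space(c("u", "v"), lower = c(-4, -4), upper = c(4, 4),
                         scale = "linear")
  f <- function(p) sum((p - c(1, -2))^2)
  set.seed(5)
  pop <- matrix(runif(20, -4, 4), 10, 2, dimnames = list(NULL, sp$names))
  st <- mgg_step(pop, NULL, f, sp, ga_control(population = 10,
                                              generations = 1,
                                              children = 6))
  best <- min(st$losses)
  for (k in 1:200) {
    st <- mgg_step(st$population, st$losses, f, sp,
                   ga_control(population = 10, generations = 1,
                              children = 6))
    expect_lte(min(st$losses), best)
    best <- min(st$losses)
  }
  # bounds respected after repair
  expect_true(all(st$population >= -4 & st$population <= 4))
})

test_that("MGG tolerates objective failures within a family", {
  sp <- llv_search_space("u", lower = -1, upper = 1, scale = "linear")
  f <- function(p) if (p[1L] > 0) Inf else p[1L]^2  # half the box fails
  set.seed(2)
  pop <- matrix(runif(6, -1, 1), 6, 1, dimnames = list(NULL, "u"))
  st <- list(population = pop, losses = NULL)
  for (k in 1:50)
    st <- mgg_step(st$population, st$losses, f, sp,
                   ga_control(population = 6, generations = 1, children = 4))
  expect_true(all(is.finite(st$losses) | st$losses == Inf))
  expect_lt(min(st$losses), 1e-2)
})

test_that("fixed seeds make the GA bit-reproducible", {
  sp <- llv_search_space(c("u", "v", "w"), lower = rep(-5, 3),
                         upper = rep(5, 3), scale = "linear")
  f <- function(p) sum((p - c(1, -2, 3))^2)
  ctl <- ga_control(population = 20, generations = 15, children = 8,
                    seed = 99)
  r1 <- rcga_optimize(f, sp, ctl)
  r2 <- rcga_optimize(f, sp, ctl)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$loss, r2$loss)
})

test_that("the GA recovers a known optimum inside the box", {
  sp <- llv_search_space(c("u", "v", "w"), lower = rep(-5, 3),
                         upper = rep(5, 3), scale = "linear")
  target <- c(1, -2, 3)
  f <- function(p) sum((p - target)^2)
  fit <- rcga_optimize(f, sp, fast_ctrl(1))
  expect_true(all(abs(fit$par - target) < 1e-3))
  expect_true(all(diff(fit$history) <= 0))
  expect_equal(fit$evaluations,
               40 + 50 * 20 * 20)  # init + generations * families * children
})

test_that("all evaluated candidates respect the box bounds", {
  lower <- c(1e-4, 10); upper <- c(1, 1000)
  sp <- llv_search_space(c("u", "v"), lower = lower, upper = upper)
  seen_bad <- FALSE
  f <- function(p) {
    if (any(p < lower - 1e-12) || any(p > upper + 1e-12))
      seen_bad <<- TRUE
    (log10(p[1L]) + 2)^2 + (log10(p[2L]) - 2)^2
  }
  fit <- rcga_optimize(f, sp, ga_control(population = 12, generations = 20,
                                         children = 6, seed = 4))
  expect_false(seen_bad)
  expect_equal(unname(fit$par), c(1e-2, 100), tolerance = 1e-3)
})

test_that("log10 search is invariant under a power-of-ten unit change", {
  sp1 <- llv_search_space("u", lower = 1e-4, upper = 1)
  sp2 <- llv_search_space("u", lower = 1e-3, upper = 10)
  f1 <- function(p) (log10(p[1L]) + 2)^2
  f2 <- function(p) (log10(p[1L] / 10) + 2)^2
  ctl <- ga_control(population = 12, generations = 10, children = 6,
                    seed = 21)
  r1 <- rcga_optimize(f1, sp1, ctl)
  r2 <- rcga_optimize(f2, sp2, ctl)
  expect_equal(r2$par / r1$par, c(u = 10), tolerance = 1e-12)
  expect_equal(r1$history, r2$history, tolerance = 1e-12)
})

test_that("growth fit recovers noiseless generating parameters", {
  g <- neg_pars()
  obs <- synthesize_timeseries(g, noise = noise_model(cv = 0), step = 0.01)
  fit <- llv_fit(obs, "growth", control = fast_ctrl(8), step = 0.1)
  truth <- c(a = g$a, b = g$b, x0 = g$x0)
  expect_true(all(abs(coef(fit) - truth) / truth < 0.05))
  # the optimum beats perturbed parameter vectors
  for (fac in c(0.8, 1.2)) {
    pert <- llv_params(a = g$a * fac, b = g$b, x0 = g$x0)
    expect_lt(fit$loss, llv_evaluate(pert, obs, step = 0.1)$loss)
  }
})

test_that("degenerate flat data still yields a finite growth fit", {
  flat <- llv_timeseries(assay_times(), rep(5e5, 10))
  fit <- llv_fit(flat, "growth", control = fast_ctrl(3, population = 20,
                                                     generations = 20,
                                                     children = 8),
                 step = 0.1)
  expect_true(is.finite(fit$loss))
})

test_that("apoptosis fit holds the growth parameters fixed", {
  g <- neg_pars()
  p <- sirna_pars("ACD")
  obs <- synthesize_timeseries(p, noise = noise_model(cv = 0), step = 0.01)
  fit <- llv_fit(obs, "apoptosis", growth = g, control = fast_ctrl(12),
                 step = 0.1)
  expect_identical(coef(fit, full = TRUE)[c("a", "b", "x0")],
                   c(a = g$a, b = g$b, x0 = g$x0))
  expect_setequal(names(coef(fit)), c("c", "d", "y0"))
  truth <- c(c = p$c, d = p$d, y0 = p$y0)
  expect_true(all(abs(coef(fit)[names(truth)] - truth) / truth < 0.10))
})

test_that("fitting negative-control-shaped data drives the effect to zero", {
  g <- neg_pars()
  obs <- synthesize_timeseries(g, noise = noise_model(cv = 0), step = 0.01)
  fit <- llv_fit(obs, "apoptosis", growth = g, control = fast_ctrl(5),
                 step = 0.1)
  traj <- llv_integrate(fit$params, 0, 92.7, 0.1)
  # total apoptotic pressure relative to total growth pressure
  expect_lt(fit$params$e * traj_auc(traj, "y") / (g$a * 92.7), 0.01)
})
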