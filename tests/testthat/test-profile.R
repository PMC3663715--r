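test_that("trapezoid areas are exact for constant and linear profiles", {
  tg <- seq(0, 1, by = 0.01)
  const <- llv_trajectory(tg, x = rep(2, length(tg)), y = rep(3, length(tg)),
                          step = 0.01)
  expect_equal(traj_auc(const, "y"), 3, tolerance = 1e-12)
  expect_equal(traj_auc(const, "y", window = c(0.25, 0.75)), 1.5,
               tolerance = 1e-12)
  lin <- llv_trajectory(tg, x = rep(1, length(tg)), y = tg, step = 0.01)
  expect_equal(traj_auc(lin, "y"), 0.5, tolerance = 1e-6)
  # window endpoints between grid points are interpolated
  expect_equal(traj_auc(lin, "y", window = c(0.005, 0.995)),
               (0.995^2 - 0.005^2) / 2, tolerance = 1e-9)
  # the negative control has no strength curve at all
  neg_traj <- llv_integrate(neg_pars(), 0, 92.7, 0.1)
  expect_identical(traj_auc(neg_traj, "y"), 0)
})

test_that("accumulated population difference behaves like an area", {
  tg <- seq(0, 10, by = 0.1)
  base <- llv_trajectory(tg, x = rep(100, length(tg)), y = rep(0, length(tg)),
                         step = 0.1)
  same <- llv_trajectory(tg, x = rep(100, length(tg)), y = rep(0, length(tg)),
                         step = 0.1)
  lower <- llv_trajectory(tg, x = rep(93, length(tg)), y = rep(0, length(tg)),
                          step = 0.1)
  expect_equal(diff_effect(base, same), 0)
  expect_equal(diff_effect(base, lower), 7 * 10, tolerance = 1e-12)
  # strong siRNA kills more cells than a weak one
  w <- c(0, 92.7)
  neg_traj <- llv_integrate(neg_pars(), 0, 92.7, 0.01)
  acd <- llv_integrate(sirna_pars("ACD"), 0, 92.7, 0.01)
  mp <- llv_integrate(sirna_pars("MP"), 0, 92.7, 0.01)
  expect_gt(diff_effect(neg_traj, acd, w), diff_effect(neg_traj, mp, w))
  expect_gt(diff_effect(neg_traj, mp, w), 0)
})

test_that("peak height is the grid maximum within the window", {
  tg <- seq(0, 1, by = 0.01)
  rising <- llv_trajectory(tg, x = rep(1, length(tg)), y = tg^2, step = 0.01)
  expect_identical(peak_height(rising), 1)
  expect_identical(peak_height(rising, window = c(0, 0.5)),
                   max(tg[tg <= 0.5])^2)
  flat0 <- llv_trajectory(tg, x = rep(1, length(tg)), y = rep(0, length(tg)),
                          step = 0.01)
  expect_identical(peak_height(flat0), 0)
  # the reconstructed strength grows before cells are depleted
  kif <- llv_integrate(sirna_pars("KIF"), 0, 92.7, 0.01)
  expect_gt(peak_height(kif, c(0, 92.7)), 8.382e-3)
})

test_that("profile summaries cover the panel with sane magnitudes", {
  panel <- code_panel()
  prof <- profile_summaries(panel[sirna_names()], panel$Neg, step = 0.02)
  expect_s3_class(prof, "llv_profiles")
  expect_identical(prof$name, sirna_names())
  expect_true(all(is.finite(as.matrix(prof[-1L]))))
  expect_true(all(prof$diff >= 0 & prof$sirna_auc >= 0))
  expect_true(all(prof$height >= vapply(panel[sirna_names()],
                                        function(p) p$y0, numeric(1L))))
  # every strong-group accumulated difference exceeds every weak one
  strong <- prof$diff[prof$name %in% c("ACD", "KIF", "PLK")]
  weak <- prof$diff[prof$name %in% c("VHP", "HP", "MP")]
  expect_gt(min(strong), max(weak))
  # zero-length window: areas vanish, height is the instantaneous value
  inst <- profile_summaries(panel["ACD"], panel$Neg, window = c(50, 50),
                            step = 0.1)
  expect_identical(inst$diff, 0)
  expect_identical(inst$sirna_auc, 0)
  traj <- llv_integrate(panel$ACD, 0, 92.7, 0.1)
  expect_equal(inst$height, sample_at(traj, 50, "y"))
})

test_that("covariance PCA of (c, d) is dominated by d on raw scales", {
  panel <- code_panel()
  cv <- vapply(panel[sirna_names()], function(p) p$c, numeric(1L))
  dv <- vapply(panel[sirna_names()], function(p) p$d, numeric(1L))
  pc <- pca_cd(cv, dv)
  expect_equal(sum(pc$loadings^2), 1)
  expect_gt(pc$loadings[["d"]], 0)
  expect_gt(cor(pc$scores, dv), 0.999)
  # with covariance scaling PC1 is numerically the d axis, so its
  # correlation with c collapses onto corr(c, d) (frozen regression)
  expect_equal(cor(pc$scores, cv), 0.7926377, tolerance = 5e-6)
  # symmetric cloud: equal loadings
  pts <- c(1, 2, 4, 7)
  pcs <- pca_cd(pts, pts)
  expect_equal(unname(pcs$loadings), c(1, 1) / sqrt(2), tolerance = 1e-12)
  # translation invariance of scores (sign-fixed)
  pc2 <- pca_cd(cv + 5, dv + 11)
  expect_equal(pc2$scores, pc$scores, tolerance = 1e-9)
  expect_error(pca_cd(rep(1, 4), rep(2, 4)), "degenerate")
  expect_error(pca_cd(1:2, 2:3), "3 points")
})

test_that("correlation report reproduces the reference parameter cells", {
  panel <- code_panel()
  prof <- profile_summaries(panel[sirna_names()], panel$Neg, step = 0.02)
  rep_ <- profile_correlations(prof)
  M <- rep_$matrix
  expect_identical(rep_$labels, c("Diff.", "siRNA", "height", "c", "d",
                                  "PC1"))
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(abs(M) <= 1 + 1e-12))
  # the pure-parameter cell needs no integration and is exact
  expect_equal(M["c", "d"], 0.79264, tolerance = 5e-4)
  # correlations are invariant to positive affine rescaling of a measure
  prof2 <- prof
  prof2$diff <- prof2$diff * 3.7 + 11
  M2 <- profile_correlations(prof2)$matrix
  expect_equal(M2, M, tolerance = 1e-9)
})

test_that("zero-variance measures are flagged undefined, not silent NaN", {
  prof <- structure(data.frame(name = c("s1", "s2", "s3"),
                               diff = c(1, 1, 1), sirna_auc = c(1, 2, 3),
                               height = c(2, 1, 4), c = c(1e-8, 2e-8, 3e-8),
                               d = c(0.1, 0.2, 0.05)),
                    class = c("llv_profiles", "data.frame"))
  expect_warning(rep_ <- profile_correlations(prof), "zero-variance")
  expect_true(all(is.na(rep_$matrix["Diff.", colnames(rep_$matrix) !=
                                              "Diff."])))
  expect_identical(rep_$matrix["Diff.", "Diff."], 1)
})

test_that("the panel splits into the strong and weak groups", {
  panel <- code_panel()
  prof <- profile_summaries(panel[sirna_names()], panel$Neg, step = 0.1)
  grp <- classify_strength(prof)
  expect_identical(names(grp)[grp == "strong"], c("ACD", "KIF", "PLK"))
  expect_identical(names(grp)[grp == "weak"], c("VHP", "HP", "MP"))
  # two points: one per group
  two <- data.frame(c = c(1e-7, 1e-8), d = c(0.1, 1e-7))
  g2 <- classify_strength(two)
  expect_identical(as.character(g2), c("strong", "weak"))
  # identical points: degenerate single group, warned
  same <- data.frame(c = rep(1e-7, 3), d = rep(0.1, 3))
  expect_warning(g3 <- classify_strength(same), "degenerate")
  expect_true(all(g3 == "strong"))
})

test_that("the phenotypic score is the fitted incorporation rate", {
  expect_identical(phenotypic_score(sirna_pars("ACD")), 2.694e-7)
  panel <- code_panel()
  scores <- vapply(panel[sirna_names()], phenotypic_score, numeric(1L))
  expect_identical(names(which.max(scores)), "ACD")
  expect_identical(names(which.min(scores)), "MP")
  # a growth fit carries no apoptotic arm
  obs <- synthesize_timeseries(neg_pars(), noise = noise_model(cv = 0))
  fit <- llv_fit(obs, "growth", step = 0.1,
                 control = fast_ctrl(2, population = 12, generations = 5,
                                     children = 4))
  expect_identical(phenotypic_score(fit), 0)
})
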