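test_that("design effect and effective N follow the closed forms", {
  expect_equal(design_effect(1, 0.7), 1)
  expect_equal(design_effect(10, 1), 10)
  expect_equal(design_effect(5, 0.5), 3)
  expect_equal(design_effect(7, 0), 1)
  expect_error(design_effect(0.5, 0.2), "n")
  expect_error(design_effect(5, 1.2), "icc")

  expect_equal(effective_n(220, 1), 220)
  expect_equal(effective_n(220, 10), 22)
  expect_equal(effective_n(110, 3), 110 / 3)
  expect_error(effective_n(100, 0.9), "deff")
})

test_that("theoretical underestimation/overestimation match hand values", {
  expect_equal(se_underestimation_theoretical(13, 0), 0)
  expect_equal(se_underestimation_theoretical(10, 0.5),
               (sqrt(5.5) - 1) / sqrt(5.5) * 100)  # 57.36
  expect_equal(se_underestimation_theoretical(5, 0.5),
               (sqrt(3) - 1) / sqrt(3) * 100)      # 42.26

  expect_equal(t_overestimation_theoretical(7, 0), 0)
  expect_equal(t_overestimation_theoretical(5, 0.5),
               (sqrt(3) - 1) * 100)
  expect_equal(t_overestimation_theoretical(10, 1),
               (sqrt(10) - 1) * 100)

  expect_equal(efficacy_loss(10, 0), 0)
  expect_equal(efficacy_loss(10, 1), 90)
  expect_equal(efficacy_loss(5, 0.1), (1 - 1 / 1.4) * 100)
})

test_that("the two theoretical curves are two faces of sqrt(Deff)", {
  grid <- expand.grid(n = seq(1, 50, length.out = 50),
                      icc = seq(0, 1, length.out = 50))
  lhs <- (1 + t_overestimation_theoretical(grid$n, grid$icc) / 100) *
    (1 - se_underestimation_theoretical(grid$n, grid$icc) / 100)
  expect_lt(max(abs(lhs - 1)), 1e-10)
})

test_that("both curves increase strictly in ICC and cluster size", {
  iccs <- seq(0.05, 1, by = 0.05)
  for (n in c(2, 5, 10)) {
    expect_true(all(diff(se_underestimation_theoretical(n, iccs)) > 0))
    expect_true(all(diff(t_overestimation_theoretical(n, iccs)) > 0))
  }
  ns <- 2:30
  for (icc in c(0.1, 0.5, 0.9)) {
    expect_true(all(diff(se_underestimation_theoretical(ns, icc)) > 0))
    expect_true(all(diff(t_overestimation_theoretical(ns, icc)) > 0))
  }
})

test_that("observed metrics use the stated sign conventions", {
  expect_equal(se_underestimation_observed(1, 1), 0)
  expect_equal(se_underestimation_observed(2, 1), 50)
  expect_equal(se_underestimation_observed(1, 1.2), -20)  # MLM smaller
  expect_error(se_underestimation_observed(0, 1), "se_mlm")

  expect_equal(t_overestimation_observed(2, 2), 0)
  expect_equal(t_overestimation_observed(3, 2), 50)
  expect_error(t_overestimation_observed(1, 0), "undefined")
})

test_that("t-score overestimation reduces to the design-effect form", {
  # construct t_lm = beta * sqrt(Deff) / se, t_mlm = beta / se
  beta <- 2.3
  se <- 0.11
  deff <- design_effect(10, 0.6)
  obs <- t_overestimation_observed(beta * sqrt(deff) / se, beta / se)
  expect_equal(obs, t_overestimation_theoretical(10, 0.6),
               tolerance = 1e-10)
})

test_that("correction factor and back-transformed intervals behave", {
  expect_equal(correction_factor(0), 1)
  expect_equal(correction_factor(1), exp(0.5))
  expect_equal(correction_factor(0.5), exp(0.125))
  expect_error(correction_factor(-1), "rse")

  degenerate <- back_transform_intercept_ci(1.3, 0, df = 10)
  expect_equal(unname(degenerate), rep(exp(1.3), 3))

  ci <- back_transform_intercept_ci(0, 1 / qt(0.975, 100), df = 100)
  expect_equal(unname(ci[c("lower", "upper")]), exp(c(-1, 1)),
               tolerance = 1e-9)
  # lognormal asymmetry: upper bound farther from center than lower
  expect_gt(ci["upper"] - ci["center"], ci["center"] - ci["lower"])
  # asymmetry grows with interval width
  wide <- back_transform_intercept_ci(0, 2 / qt(0.975, 100), df = 100)
  expect_equal(unname(wide["upper"] / wide["center"]),
               unname((ci["upper"] / ci["center"])^2), tolerance = 1e-9)

  expect_error(back_transform_intercept_ci(0, 1, df = 0), "df")
  expect_error(back_transform_intercept_ci(0, 1, df = 10, level = 1.2),
               "level")
})

test_that("model comparison wires the fits and metrics together", {
  d <- sim_data(icc = 0.5, J = 22, n = 10, seed = 21)
  cmp <- compare_models(d, "TB", "D")
  expect_s3_class(cmp$ols, "ols_fit")
  expect_s3_class(cmp$mlm, "mlm_fit")
  expect_equal(cmp$N, 220)
  expect_equal(cmp$J, 22)
  expect_equal(cmp$n_bar, 10)
  expect_equal(cmp$icc, cmp$mlm$icc)
  expect_equal(cmp$d, durbin_watson(cmp$ols$residuals))
  expect_equal(cmp$se_underest_obs_beta,
               (cmp$mlm$se_beta - cmp$ols$se_beta) / cmp$mlm$se_beta * 100)
  expect_equal(cmp$t_over_obs,
               (cmp$ols$t_beta - cmp$mlm$t_beta) / cmp$mlm$t_beta * 100)
  expect_error(compare_models(d, "ST", "D"), "missing|ST_g")
})

test_that("observed underestimation nearly vanishes on independent data", {
  seu <- vapply(1:100, function(r) {
    d <- generate_dataset(sim_config(J = 50, n = 10, tau2 = 0,
                                     seed = 1200 + r))
    compare_models(d, "TB", "D")$se_underest_obs_beta
  }, numeric(1))
  # tau2 is truncated at zero, so the fitted ICC (and with it the
  # observed underestimation) has a small positive bias under the null:
  # E[ICC_hat] ~ 0.008 at J = 50, n = 10, which maps through the
  # design-effect curve to about +3 points of SEu. The mean must be
  # small and non-negative, not exactly zero.
  expect_gt(mean(seu), -1)
  expect_lt(mean(seu), 6)
})

test_that("the 10-model grid yields one comparison row per model", {
  d <- sim_data(icc = 0.5, J = 22, n = 5, seed = 23, components = TRUE)
  tab <- compare_all_models(d)
  expect_equal(nrow(tab), 10)
  expect_equal(nrow(unique(tab[, c("response", "predictor")])), 10)
  expect_true(all(tab$icc >= 0 & tab$icc < 1))
  expect_true(all(tab$d >= 0 & tab$d <= 4))
  expect_true(all(tab$se_beta_mlm > 0))
})

test_that("design-effect report is internally consistent", {
  rep <- design_effect_report(n = 10, icc = 0.5, N = 220)
  expect_equal(rep$deff, 5.5)
  expect_equal(rep$n_effective, 40)
  expect_equal((1 + rep$t_over_theory / 100) *
                 (1 - rep$se_underest_theory / 100), 1,
               tolerance = 1e-12)
})
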