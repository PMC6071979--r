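test_that("OLS reproduces closed-form normal-equation solutions", {
  exact <- fit_ols(c(1, 2, 3), c(2, 4, 6))
  expect_equal(exact$beta_hat, 2)
  expect_equal(exact$alpha_hat, 0, tolerance = 1e-12)
  expect_equal(exact$rse, 0, tolerance = 1e-12)

  hand <- fit_ols(c(1, 2, 3), c(1, 2, 2))  # Sxy = 1, Sxx = 2
  expect_equal(hand$beta_hat, 0.5)
  expect_equal(hand$alpha_hat, 2 / 3)
  expect_equal(sum(hand$residuals), 0, tolerance = 1e-12)
  expect_equal(hand$df, 1)
  expect_equal(hand$t_beta, hand$beta_hat / hand$se_beta)
})

test_that("a single-point perturbation moves the slope by its leverage", {
  set.seed(4)
  x <- rnorm(20)
  y <- 1 + 2 * x + rnorm(20)
  base <- fit_ols(x, y)
  delta <- 0.37
  i <- 7
  y2 <- y
  y2[i] <- y2[i] + delta
  pert <- fit_ols(x, y2)
  sxx <- sum((x - mean(x))^2)
  expect_equal(pert$beta_hat - base$beta_hat,
               delta * (x[i] - mean(x)) / sxx, tolerance = 1e-10)
})

test_that("OLS agrees with lm() on simulated data", {
  d <- sim_data(icc = 0.5, J = 10, n = 5, seed = 2)
  y <- log(d$TB_g)
  x <- log(d$D_mm)
  mine <- fit_ols(x, y)
  ref <- lm(y ~ x)
  expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(sqrt(diag(mine$vcov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-10)
  expect_equal(mine$rse, summary(ref)$sigma, tolerance = 1e-10)
})

test_that("OLS rejects degenerate designs", {
  expect_error(fit_ols(c(1, 1, 1), c(1, 2, 3)), "singular")
  expect_error(fit_ols(c(1, 2), c(1, 2)), "insufficient")
})

test_that("REML equals the balanced ANOVA decomposition by hand", {
  toy <- balanced_toy()  # stand means 1 and 5: MSB = 16, MSW = 2
  f <- fit_random_intercept_reml(toy$y, toy$stand)
  expect_equal(f$sigma2, 2, tolerance = 1e-6)
  expect_equal(f$tau2, 7, tolerance = 1e-6)
  expect_equal(f$icc, 7 / 9, tolerance = 1e-6)
  expect_false(f$boundary)
  expect_true(f$converged)
  expect_equal(f$alpha_hat, 3, tolerance = 1e-8)  # grand mean, balanced

  av <- anova_variance_components(toy$y, toy$stand)
  expect_equal(av$sigma2, 2)
  expect_equal(av$tau2, 7)
  expect_equal(av$msb, 16)
})

test_that("negative moment estimates are truncated at the boundary", {
  f <- fit_random_intercept_reml(c(0, 2, 2, 0), c("A", "A", "B", "B"))
  expect_equal(f$tau2, 0)
  expect_equal(f$icc, 0)
  expect_true(f$boundary)

  av <- anova_variance_components(c(1, 1, 5, 5), c("A", "A", "B", "B"))
  expect_equal(av$sigma2, 0)   # MSW = 0
  expect_equal(av$tau2, 8)     # (MSB - 0) / n = 16 / 2
})

test_that("degenerate and malformed inputs are handled explicitly", {
  expect_warning(f <- fit_random_intercept_reml(rep(3, 6),
                                                rep(c("A", "B"), 3)),
                 "zero variance")
  expect_equal(c(f$tau2, f$sigma2, f$icc), c(0, 0, 0))
  expect_warning(av <- anova_variance_components(rep(1, 4),
                                                 c("A", "A", "B", "B")),
                 "zero variance")
  expect_equal(c(av$sigma2, av$tau2), c(0, 0))

  expect_error(fit_random_intercept_reml(1:4, rep("A", 4)),
               "single stand|between-stand")
  expect_error(anova_variance_components(1:5, c("A", "A", "A", "B", "B")),
               "unsupported")
})

test_that("REML matches the ANOVA oracle on balanced interior cases", {
  set.seed(101)
  for (i in 1:12) {
    rb <- random_balanced(J = sample(8:15, 1), n = sample(3:6, 1))
    av <- anova_variance_components(rb$y, rb$stand)
    if (av$tau2 == 0 || av$boundary) next
    f <- fit_random_intercept_reml(rb$y, rb$stand)
    expect_lt(abs(f$tau2 - av$tau2) / av$tau2, 1e-4)
    expect_lt(abs(f$sigma2 - av$sigma2) / av$sigma2, 1e-4)
  }
})

test_that("optimizer beats a brute-force profile grid", {
  set.seed(55)
  for (i in 1:5) {
    rb <- random_balanced(J = 10, n = 4)
    f <- fit_random_intercept_reml(rb$y, rb$stand)
    grid <- exp(seq(log(1e-6), log(1e6), length.out = 200))
    best_grid <- max(reml_profile_loglik(grid, rb$y, rb$stand))
    expect_gte(f$loglik, best_grid - 1e-6)
  }
})

test_that("REML with a covariate agrees with lme4 on clustered data", {
  skip_if_not_installed("lme4")
  d <- sim_data(icc = 0.4, J = 22, n = 10, seed = 6)
  y <- log(d$TB_g)
  x <- log(d$D_mm)
  mine <- fit_random_intercept_reml(y, d$stand_id, x)
  ref <- lme4::lmer(y ~ x + (1 | sid),
                    data = data.frame(y = y, x = x, sid = d$stand_id),
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))$vcov
  expect_equal(mine$tau2, vc[1], tolerance = 1e-5)
  expect_equal(mine$sigma2, vc[2], tolerance = 1e-5)
  expect_equal(unname(mine$coef), unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(mine$vcov))),
               unname(sqrt(diag(as.matrix(vcov(ref))))), tolerance = 1e-5)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  # BLUPs match too
  blup <- lme4::ranef(ref)$sid
  expect_equal(unname(mine$u[rownames(blup)]), blup[["(Intercept)"]],
               tolerance = 1e-5)
})

test_that("REML handles unbalanced designs (cross-checked with lme4)", {
  skip_if_not_installed("lme4")
  d <- sim_data(icc = 0.5, J = 12, n = 8, seed = 9)
  d <- d[-c(1, 2, 3, 9, 17, 30), ]  # unbalance a few stands
  y <- log(d$TB_g)
  x <- log(d$D_mm)
  mine <- fit_random_intercept_reml(y, d$stand_id, x)
  ref <- lme4::lmer(y ~ x + (1 | sid),
                    data = data.frame(y = y, x = x, sid = d$stand_id),
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))$vcov
  expect_equal(mine$tau2, vc[1], tolerance = 1e-5)
  expect_equal(mine$sigma2, vc[2], tolerance = 1e-5)
  expect_equal(unname(mine$coef), unname(lme4::fixef(ref)),
               tolerance = 1e-6)
})

test_that("multilevel fit collapses to OLS when the fitted ICC is zero", {
  # independent data usually truncates tau2 to 0; then GLS == OLS
  set.seed(31)
  found <- FALSE
  for (i in 1:20) {
    d <- generate_dataset(sim_config(J = 20, n = 8, tau2 = 0,
                                     seed = 300 + i))
    y <- log(d$TB_g)
    x <- log(d$D_mm)
    m <- fit_random_intercept_reml(y, d$stand_id, x)
    if (m$icc != 0) next
    found <- TRUE
    o <- fit_ols(x, y)
    expect_lt(abs(m$beta_hat - o$beta_hat) / abs(o$beta_hat), 1e-3)
    expect_lt(abs(m$se_beta - o$se_beta) / o$se_beta, 1e-3)
    break
  }
  expect_true(found)
})

test_that("both slope estimators are unbiased for the generating exponent", {
  est <- t(vapply(1:60, function(r) {
    d <- generate_dataset(sim_config(J = 22, n = 5,
                                     tau2 = tau2_for_icc(0.5),
                                     seed = 8000 + r))
    y <- log(d$TB_g)
    x <- log(d$D_mm)
    c(lm = fit_ols(x, y)$beta_hat,
      mlm = fit_random_intercept_reml(y, d$stand_id, x)$beta_hat)
  }, numeric(2)))
  expect_lt(abs(mean(est[, "lm"]) - 2.4), 0.02)
  expect_lt(abs(mean(est[, "mlm"]) - 2.4), 0.02)
})

test_that("ICC estimates pile on the boundary under a true null", {
  res <- vapply(1:100, function(r) {
    d <- generate_dataset(sim_config(J = 50, n = 10, tau2 = 0,
                                     seed = 900 + r))
    f <- fit_random_intercept_reml(log(d$TB_g), d$stand_id, log(d$D_mm))
    c(f$icc, f$boundary)
  }, numeric(2))
  expect_gte(mean(res[2, ]), 0.4)  # boundary mass
  expect_lt(mean(res[1, ]), 0.02)  # mean fitted ICC near zero
})

test_that("named t-scores survive multi-predictor designs", {
  d <- sim_data(icc = 0.3, J = 10, n = 6, seed = 13)
  y <- log(d$TB_g)
  X <- cbind(logD = log(d$D_mm), z = rnorm(nrow(d)))
  o <- fit_ols(X, y)
  m <- fit_random_intercept_reml(y, d$stand_id, X)
  expect_named(o$t_beta, c("logD", "z"))
  expect_named(m$t_beta, c("logD", "z"))
  expect_equal(m$df_beta, nrow(d) - 10 - 2)
})
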