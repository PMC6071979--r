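# Monte-Carlo validation study: observed-vs-theoretical consequence
# curves, the ICC-versus-d regression, the mean-ICC test and (optionally)
# the type-I-error experiment, on synthetic clustered allometric data.

# Deterministic sub-seed derivation (kept below 2^31 for R's integer
# range) so every cell and replicate records a reproducible seed.
derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483629 * 7919 + i * 104729) %%
               2147483629 + 1)
}

#' Run the observed-vs-theoretical validation study
#'
#' For every cell of an (ICC, cluster size) grid, repeatedly simulates a
#' clustered dataset (`J` stands, `n` trees, target ICC), fits the OLS
#' and random-intercept models of `ln(TB)` on `ln(D)`, and averages the
#' observed standard-error underestimation and t-score overestimation.
#' These Monte-Carlo means are tabulated next to the closed-form
#' design-effect values, reproducing the observed-points-on-theoretical-
#' lines validation. The study also runs the ICC-versus-d regression
#' ([run_icc_dw_study()]) and the one-sample test of mean ICC against
#' zero.
#'
#' @param iccs Target ICC values of the grid.
#' @param ns Cluster sizes of the grid.
#' @param J Number of stands per simulated dataset.
#' @param replicates Replicates per cell.
#' @param seed Master seed; every cell and replicate derives its own
#'   recorded sub-seed, so the full study is reproducible.
#' @param sigma2 Within-stand residual variance of log biomass; `tau2`
#'   per cell is set to hit the cell's target ICC.
#' @param type1 Logical: also run [type1_error_experiment()] at each
#'   cell? Off by default (it is the expensive part).
#' @param type1_replicates Replicates for the type-I-error experiment.
#' @return Object of class `study_result`: `cells` (one row per grid
#'   cell: seed, mean/SD of observed metrics, theoretical values,
#'   boundary fraction), `icc_vs_d` (see [run_icc_dw_study()]),
#'   `mean_icc_test` (one-sample t-test of the 20 fitted ICCs against
#'   0), optional `type1`, plus `J`, `replicates`, `seed`.
#' @export
run_validation_study <- function(iccs = c(0.1, 0.3, 0.5, 0.8),
                                 ns = c(5, 10),
                                 J = 22, replicates = 200, seed = 1L,
                                 sigma2 = 0.02,
                                 type1 = FALSE,
                                 type1_replicates = 1000L) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(icc = iccs, n = ns)
  cells <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    icc <- grid$icc[g]
    n <- grid$n[g]
    cell_seed <- derive_seed(seed, g)
    seu_a <- seu_b <- tov <- icc_hat <- dvec <- numeric(replicates)
    boundary <- logical(replicates)
    for (r in seq_len(replicates)) {
      cfg <- sim_config(J = J, n = n, tau2 = tau2_for_icc(icc, sigma2),
                        sigma2 = sigma2,
                        seed = derive_seed(cell_seed, r))
      cmp <- compare_models(generate_dataset(cfg), "TB", "D")
      seu_a[r] <- cmp$se_underest_obs_alpha
      seu_b[r] <- cmp$se_underest_obs_beta
      tov[r] <- cmp$t_over_obs
      icc_hat[r] <- cmp$icc
      dvec[r] <- cmp$d
      boundary[r] <- cmp$mlm$boundary
    }
    cells[[g]] <- data.frame(
      icc = icc, n = n, J = J, replicates = replicates,
      seed = cell_seed,
      seu_alpha_obs_mean = mean(seu_a), seu_alpha_obs_sd = stats::sd(seu_a),
      seu_beta_obs_mean = mean(seu_b), seu_beta_obs_sd = stats::sd(seu_b),
      t_ovr_obs_mean = mean(tov), t_ovr_obs_sd = stats::sd(tov),
      seu_theory = se_underestimation_theoretical(n, icc),
      t_ovr_theory = t_overestimation_theoretical(n, icc),
      icc_hat_mean = mean(icc_hat), d_mean = mean(dvec),
      boundary_frac = mean(boundary)
    )
  }
  cells <- do.call(rbind, cells)

  icc_vs_d <- run_icc_dw_study(ns = ns, J = J,
                               seed = derive_seed(seed, 10007L))
  icc_test <- mean_icc_test(icc_vs_d$data$icc_hat)

  out <- list(cells = cells, icc_vs_d = icc_vs_d,
              mean_icc_test = icc_test,
              J = J, replicates = replicates, seed = seed)
  if (isTRUE(type1)) {
    out$type1 <- do.call(rbind, lapply(seq_along(iccs), function(i) {
      t1 <- type1_error_experiment(iccs[i], n = max(ns), J = J,
                                   replicates = type1_replicates,
                                   seed = derive_seed(seed, 20011L + i))
      data.frame(icc = iccs[i], n = max(ns), J = J,
                 rate_lm = t1$rate_lm, rate_mlm = t1$rate_mlm,
                 replicates = t1$replicates, seed = t1$seed)
    }))
  }
  class(out) <- "study_result"
  out
}

#' ICC-versus-Durbin-Watson regression study
#'
#' Reproduces the 20-model ICC-versus-d analysis on synthetic data: for
#' each cluster size (default 5 and 10 trees) one clustered dataset with
#' all four biomass components is simulated, the 10 models of the
#' component-by-predictor grid (5 responses times D and H) are fitted,
#' and each model contributes one point — its fitted intraclass
#' correlation and the Durbin-Watson `d` of its OLS residuals. The
#' component-specific residual variances spread the fitted ICCs over a
#' wide range (roughly 0.05 to 0.85 under the defaults). Fitted ICC is
#' then regressed on `d`; under the naive linear approximation
#' `ICC = 1 - 0.5 d` the intercept should be near 1.0 and the slope near
#' -0.5, and both are tested (t-tests against those values) and
#' interval-estimated.
#'
#' @param ns Cluster sizes, one simulated dataset per value.
#' @param J Stands per dataset.
#' @param seed Master seed.
#' @param tau2 Between-stand variance shared by all components.
#' @param level Confidence level for the parameter intervals.
#' @param sigma2 Unused placeholder for symmetry with
#'   [run_validation_study()]; component residual variances come from
#'   [default_component_params()].
#' @return List: `data` (response, predictor, n, fitted ICC, d, seed per
#'   point), `fit` (the `lm` object), `intercept`, `slope`, their
#'   standard errors, `ci_intercept`, `ci_slope`, `p_intercept_eq_1`,
#'   `p_slope_eq_minus_0.5`, `covers` (logical: both reference values
#'   inside their intervals).
#' @export
run_icc_dw_study <- function(ns = c(5, 10), J = 22, seed = 1L,
                             tau2 = 0.02, level = 0.95, sigma2 = NULL) {
  recs <- lapply(seq_along(ns), function(g) {
    s <- derive_seed(seed, g)
    cfg <- sim_config(J = J, n = ns[g], tau2 = tau2,
                      components = TRUE, seed = s)
    tab <- compare_all_models(generate_dataset(cfg))
    data.frame(response = tab$response, predictor = tab$predictor,
               n = ns[g], seed = s, icc_hat = tab$icc, d = tab$d)
  })
  data <- do.call(rbind, recs)
  fit <- stats::lm(icc_hat ~ d, data = data)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  df <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  ci_i <- cf[1] + c(-1, 1) * tcrit * se[1]
  ci_s <- cf[2] + c(-1, 1) * tcrit * se[2]
  p_i <- 2 * stats::pt(-abs((cf[1] - 1) / se[1]), df)
  p_s <- 2 * stats::pt(-abs((cf[2] + 0.5) / se[2]), df)
  list(data = data, fit = fit,
       intercept = unname(cf[1]), slope = unname(cf[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]),
       ci_intercept = ci_i, ci_slope = ci_s,
       p_intercept_eq_1 = unname(p_i),
       p_slope_eq_minus_0.5 = unname(p_s),
       covers = ci_i[1] <= 1 && 1 <= ci_i[2] &&
         ci_s[1] <= -0.5 && -0.5 <= ci_s[2],
       seed = seed)
}

#' Test whether the mean fitted ICC is zero
#'
#' One-sample t-test of the fitted intraclass correlations of a set of
#' models against zero, one-sided towards ICC > 0 (between-stand variance
#' cannot be negative). For a permutation-based alternative on a single
#' dataset see [permutation_icc_test()].
#'
#' @param iccs Vector of fitted ICC values (one per model).
#' @return `htest` object from [stats::t.test()].
#' @export
mean_icc_test <- function(iccs) {
  stats::t.test(iccs, mu = 0, alternative = "greater")
}

#' Permutation test of ICC = 0 for one dataset
#'
#' Permutes the stand labels of the dataset (destroying any true
#' clustering while keeping the marginal distributions), refits the
#' random-intercept model each time, and compares the observed fitted
#' ICC with the permutation distribution.
#'
#' @param data An `alloc_data` data frame.
#' @param response,predictor Model columns as in [compare_models()].
#' @param B Number of permutations.
#' @param seed RNG seed.
#' @return List: `icc_obs`, `p_value` (one-sided, share of permuted ICCs
#'   at least as large, with the observed value included), `icc_perm`.
#' @export
permutation_icc_test <- function(data, response = "TB", predictor = "D",
                                 B = 199, seed = 1L) {
  rcol <- resolve_column(data, response,
                         c(TB = "TB_g", ST = "ST_g", BR = "BR_g",
                           ND = "ND_g", RT = "RT_g"))
  pcol <- resolve_column(data, predictor, c(D = "D_mm", H = "H_cm"))
  y <- log(data[[rcol]])
  x <- log(data[[pcol]])
  obs <- fit_random_intercept_reml(y, data$stand_id, x)$icc
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(B), function(b) {
    fit_random_intercept_reml(y, sample(data$stand_id), x)$icc
  }, numeric(1))
  list(icc_obs = obs,
       p_value = (1 + sum(perm >= obs)) / (B + 1),
       icc_perm = perm)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Validation study: J = %d stands, %d replicates per cell, seed %d\n",
              x$J, x$replicates, x$seed))
  cols <- c("icc", "n", "seu_beta_obs_mean", "seu_theory",
            "t_ovr_obs_mean", "t_ovr_theory", "icc_hat_mean")
  print(round(x$cells[, cols], 2))
  cat(sprintf("ICC ~ d regression: intercept %.3f (ref 1.0, P = %.3f), slope %.3f (ref -0.5, P = %.3f)\n",
              x$icc_vs_d$intercept, x$icc_vs_d$p_intercept_eq_1,
              x$icc_vs_d$slope, x$icc_vs_d$p_slope_eq_minus_0.5))
  cat(sprintf("Mean fitted ICC = %.3f; H0: mean ICC = 0, P = %.2g\n",
              mean(x$icc_vs_d$data$icc_hat),
              x$mean_icc_test$p.value))
  if (!is.null(x$type1)) {
    cat("Type-I-error rates (true-null covariate slope, 5% level):\n")
    print(round(x$type1[, c("icc", "n", "rate_lm", "rate_mlm")], 3))
  }
  invisible(x)
}

#' Observed-versus-theoretical overlay plot
#'
#' Plots the theoretical standard-error underestimation and t-score
#' overestimation curves as functions of ICC, one line per cluster size,
#' with the study's Monte-Carlo mean observed values overlaid as points.
#'
#' @param x A `study_result` object.
#' @param ... Unused.
#' @export
plot.study_result <- function(x, ...) {
  cells <- x$cells
  ns <- sort(unique(cells$n))
  iccs <- seq(0, 1, by = 0.01)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (panel in c("seu", "tovr")) {
    theory <- if (panel == "seu") se_underestimation_theoretical else
      t_overestimation_theoretical
    obs_col <- if (panel == "seu") "seu_beta_obs_mean" else
      "t_ovr_obs_mean"
    ymax <- max(theory(max(ns), 1), cells[[obs_col]])
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, ymax),
                   xlab = "ICC",
                   ylab = if (panel == "seu")
                     "SE underestimation (%)" else
                       "t-score overestimation (%)")
    for (i in seq_along(ns)) {
      graphics::lines(iccs, theory(ns[i], iccs), lty = i)
      sub <- cells[cells$n == ns[i], ]
      graphics::points(sub$icc, sub[[obs_col]], pch = i)
    }
    graphics::legend("topleft", legend = paste0("n = ", ns),
                     lty = seq_along(ns), pch = seq_along(ns),
                     bty = "n")
  }
  invisible(x)
}
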