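#' Compare OLS and multilevel fits of one allometric model
#'
#' Fits `ln(response) = alpha + beta * ln(predictor)` twice on the same
#' clustered dataset — by OLS (ignoring stands) and by the
#' random-intercept multilevel model — and computes the observed
#' consequence metrics: per-parameter standard-error underestimation,
#' slope t-score overestimation, the fitted ICC, and the Durbin-Watson
#' statistic of the OLS residuals in stand-then-tree order.
#'
#' @param data An `alloc_data` data frame (or compatible).
#' @param response Response column: one of `"TB"`, `"ST"`, `"BR"`,
#'   `"ND"`, `"RT"` (or the full `_g` column name).
#' @param predictor Predictor column: `"D"` or `"H"` (or the full column
#'   name).
#' @return Object of class `model_comparison`: `response`, `predictor`,
#'   `ols` (an `ols_fit`), `mlm` (an `mlm_fit`),
#'   `se_underest_obs_alpha`, `se_underest_obs_beta` (percent),
#'   `t_over_obs` (percent, slope), `icc`, `d`, `N`, `J`, `n_bar` (mean
#'   cluster size).
#' @examples
#' d <- generate_dataset(sim_config(J = 10, n = 5, seed = 3))
#' cmp <- compare_models(d, "TB", "D")
#' cmp$se_underest_obs_beta
#' @export
compare_models <- function(data, response = "TB", predictor = "D") {
  rcol <- resolve_column(data, response,
                         c(TB = "TB_g", ST = "ST_g", BR = "BR_g",
                           ND = "ND_g", RT = "RT_g"))
  pcol <- resolve_column(data, predictor, c(D = "D_mm", H = "H_cm"))
  # stand-blocked order: clustering shows up as first-order autocorrelation
  ord <- order(match(data$stand_id, unique(data$stand_id)))
  df <- as.data.frame(data)[ord, , drop = FALSE]
  if (anyNA(df[[rcol]]) || anyNA(df[[pcol]])) {
    stop("missing values in `", rcol, "` or `", pcol, "`", call. = FALSE)
  }
  y <- log(df[[rcol]])
  x <- log(df[[pcol]])
  ols <- fit_ols(x, y)
  mlm <- fit_random_intercept_reml(y, df$stand_id, x)
  out <- list(
    response = response, predictor = predictor,
    ols = ols, mlm = mlm,
    se_underest_obs_alpha = se_underestimation_observed(mlm$se_alpha,
                                                        ols$se_alpha),
    se_underest_obs_beta = se_underestimation_observed(mlm$se_beta,
                                                       ols$se_beta),
    t_over_obs = t_overestimation_observed(ols$t_beta, mlm$t_beta),
    icc = mlm$icc,
    d = durbin_watson(ols$residuals),
    N = ols$N, J = mlm$J,
    n_bar = mean(cluster_sizes(df))
  )
  class(out) <- "model_comparison"
  out
}

resolve_column <- function(data, name, aliases) {
  col <- if (name %in% names(aliases)) aliases[[name]] else name
  if (!col %in% names(data)) {
    stop("column `", col, "` not found in dataset", call. = FALSE)
  }
  col
}

#' Compare OLS and multilevel fits for the full model grid
#'
#' Runs [compare_models()] for every combination of the requested biomass
#' components and predictors (by default the 10-model grid of 5
#' components times diameter/height) and tabulates the results, one row
#' per model.
#'
#' @param data An `alloc_data` data frame with component biomass columns.
#' @param responses Character vector of response names.
#' @param predictors Character vector of predictor names.
#' @return Data frame with one row per model: parameter estimates and
#'   standard errors from both models, `SEu_alpha`, `SEu_beta`, `t_lm`,
#'   `t_mlm`, `t_ovr`, `icc`, `d`.
#' @export
compare_all_models <- function(data,
                               responses = c("TB", "ST", "BR", "ND",
                                             "RT"),
                               predictors = c("D", "H")) {
  grid <- expand.grid(response = responses, predictor = predictors,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cmp <- compare_models(data, grid$response[i], grid$predictor[i])
    data.frame(
      response = cmp$response, predictor = cmp$predictor,
      alpha_lm = cmp$ols$alpha_hat, se_alpha_lm = cmp$ols$se_alpha,
      beta_lm = cmp$ols$beta_hat, se_beta_lm = cmp$ols$se_beta,
      alpha_mlm = cmp$mlm$alpha_hat, se_alpha_mlm = cmp$mlm$se_alpha,
      beta_mlm = cmp$mlm$beta_hat, se_beta_mlm = cmp$mlm$se_beta,
      SEu_alpha = cmp$se_underest_obs_alpha,
      SEu_beta = cmp$se_underest_obs_beta,
      t_lm = cmp$ols$t_beta, t_mlm = cmp$mlm$t_beta,
      t_ovr = cmp$t_over_obs,
      icc = cmp$icc, d = cmp$d,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: ln(%s) ~ ln(%s), N = %d trees, J = %d stands\n",
              x$response, x$predictor, x$N, x$J))
  cat(sprintf("  slope: OLS %.4f (SE %.4f), MLM %.4f (SE %.4f)\n",
              x$ols$beta_hat, x$ols$se_beta,
              x$mlm$beta_hat, x$mlm$se_beta))
  cat(sprintf("  fitted ICC = %.4f; Durbin-Watson d = %.4f\n",
              x$icc, x$d))
  cat(sprintf("  SE underestimation: intercept %.2f%%, slope %.2f%%\n",
              x$se_underest_obs_alpha, x$se_underest_obs_beta))
  cat(sprintf("  t-score overestimation (slope): %.2f%%\n", x$t_over_obs))
  invisible(x)
}
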