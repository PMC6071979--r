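# Design-effect arithmetic: the consequence metrics of ignoring a
# clustered sampling design. All are elementary functions of the cluster
# size n and the intraclass correlation coefficient (ICC), vectorized.

check_n_icc <- function(n, icc) {
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("`n` must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(icc)) || any(icc < 0 | icc > 1)) {
    stop("`icc` must lie in [0, 1]", call. = FALSE)
  }
}

#' Design effect of a clustered sample
#'
#' `Deff = 1 + (n - 1) * ICC`: the factor by which the sampling variance
#' is inflated, relative to an independent sample of the same size, when
#' `n` observations are drawn from each cluster and a fraction `ICC` of
#' the residual variance is between-cluster. `Deff = 1` when `n = 1` or
#' `ICC = 0` (independent data); `Deff = n` when `ICC = 1`.
#'
#' @param n Cluster size (>= 1; may be a non-integer average cluster size
#'   for unbalanced designs).
#' @param icc Intraclass correlation coefficient in `[0, 1]`.
#' @return The design effect (vectorized).
#' @examples
#' design_effect(10, 0.5)  # 5.5
#' @export
design_effect <- function(n, icc) {
  check_n_icc(n, icc)
  1 + (n - 1) * icc
}

#' Effective number of observations
#'
#' The number of fully independent observations carrying the same
#' information as `N` clustered ones: `N / Deff`. Equals `N` for
#' independent data and the number of clusters when `ICC = 1` in a
#' balanced design.
#'
#' @param N Actual number of observations (>= 1).
#' @param deff Design effect (>= 1).
#' @return `N / deff`.
#' @examples
#' effective_n(220, design_effect(10, 1))  # 22 = number of stands
#' @export
effective_n <- function(N, deff) {
  if (any(N < 1)) stop("`N` must be >= 1", call. = FALSE)
  if (any(deff < 1)) stop("`deff` must be >= 1", call. = FALSE)
  N / deff
}

#' Theoretical underestimation of standard errors (percent)
#'
#' When OLS is used on clustered data, log-scale standard errors are too
#' small by the factor `sqrt(Deff)`; the relative shortfall is
#' `(sqrt(Deff) - 1) / sqrt(Deff) * 100` percent. Monotone non-decreasing
#' in both `n` and `icc`.
#'
#' @inheritParams design_effect
#' @return Percent underestimation in `[0, 100)`.
#' @examples
#' se_underestimation_theoretical(10, 0.5)  # 57.36
#' @export
se_underestimation_theoretical <- function(n, icc) {
  s <- sqrt(design_effect(n, icc))
  (s - 1) / s * 100
}

#' Observed underestimation of standard errors (percent)
#'
#' `(SE_mlm - SE_lm) / SE_mlm * 100`: how much smaller the OLS standard
#' error is than the multilevel-model standard error for the same
#' parameter. Negative values are possible (and reported as-is) when the
#' fitted ICC is zero and the MLM standard error is the smaller one.
#'
#' @param se_mlm Standard error from the multilevel model (> 0).
#' @param se_lm Standard error from the OLS model.
#' @return Percent underestimation (at most 100).
#' @export
se_underestimation_observed <- function(se_mlm, se_lm) {
  if (any(se_mlm <= 0)) stop("`se_mlm` must be > 0", call. = FALSE)
  (se_mlm - se_lm) / se_mlm * 100
}

#' Theoretical overestimation of the t-score (percent)
#'
#' Under the approximation that OLS and multilevel slopes coincide, the
#' OLS t-score exceeds the correct one by `(sqrt(Deff) - 1) * 100`
#' percent.
#'
#' @inheritParams design_effect
#' @return Percent overestimation (>= 0).
#' @examples
#' t_overestimation_theoretical(5, 0.5)  # 73.21
#' @export
t_overestimation_theoretical <- function(n, icc) {
  (sqrt(design_effect(n, icc)) - 1) * 100
}

#' Observed overestimation of the t-score (percent)
#'
#' `(t_lm - t_mlm) / t_mlm * 100`, comparing the OLS and multilevel-model
#' t-scores of the same parameter.
#'
#' @param t_lm OLS t-score.
#' @param t_mlm Multilevel-model t-score (non-zero).
#' @return Percent overestimation.
#' @export
t_overestimation_observed <- function(t_lm, t_mlm) {
  if (any(t_mlm == 0)) {
    stop("undefined ratio: `t_mlm` is zero", call. = FALSE)
  }
  (t_lm - t_mlm) / t_mlm * 100
}

#' Efficacy loss from clustered sampling (percent)
#'
#' `(1 - 1 / Deff) * 100`: the share of per-observation information
#' forfeited to clustering. Zero for independent data; approaches
#' `(1 - 1/n) * 100` as the ICC approaches 1.
#'
#' @inheritParams design_effect
#' @return Percent efficacy loss in `[0, 100)`.
#' @examples
#' efficacy_loss(10, 1)  # 90
#' @export
efficacy_loss <- function(n, icc) {
  (1 - 1 / design_effect(n, icc)) * 100
}

#' Lognormal back-transformation correction factor
#'
#' `lambda = exp(RSE^2 / 2)`: the multiplicative correction applied to
#' predictions back-transformed from a natural-log-scale model, where
#' `RSE` is the residual standard error on the log scale.
#'
#' @param rse Log-scale residual standard error (>= 0).
#' @return Correction factor `>= 1`.
#' @examples
#' correction_factor(0.5)  # 1.1331
#' @export
correction_factor <- function(rse) {
  if (any(rse < 0)) stop("`rse` must be >= 0", call. = FALSE)
  exp(rse^2 / 2)
}

#' Back-transformed confidence interval of the intercept
#'
#' Computes the `level` confidence interval of the intercept on the log
#' scale, `alpha_log +/- t_crit * se_alpha`, and exponentiates the
#' bounds. Because the interval is symmetric on the log scale, the
#' arithmetic-scale interval is asymmetric around `exp(alpha_log)`: the
#' upper bound is farther from the center than the lower bound, the more
#' so the wider the log-scale interval.
#'
#' @param alpha_log Intercept estimate on the log scale.
#' @param se_alpha Its standard error (>= 0).
#' @param df Degrees of freedom for the t quantile (>= 1).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named vector `c(lower, center, upper)` on the arithmetic
#'   scale.
#' @export
back_transform_intercept_ci <- function(alpha_log, se_alpha, df,
                                        level = 0.95) {
  if (se_alpha < 0) stop("`se_alpha` must be >= 0", call. = FALSE)
  if (!is.finite(df) || df < 1) stop("invalid `df`", call. = FALSE)
  if (level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  half <- tcrit * se_alpha
  c(lower = exp(alpha_log - half),
    center = exp(alpha_log),
    upper = exp(alpha_log + half))
}

#' Theoretical consequence report for one design
#'
#' Bundles the design-effect-based metrics for a cluster size and ICC:
#' design effect, effective number of observations, theoretical
#' standard-error underestimation, t-score overestimation and efficacy
#' loss.
#'
#' @param n Cluster size.
#' @param icc Intraclass correlation coefficient.
#' @param N Total number of observations; defaults to `n` times one
#'   cluster, supply `J * n` for a full design.
#' @return Object of class `deff_report` (a list).
#' @examples
#' design_effect_report(n = 10, icc = 0.5, N = 220)
#' @export
design_effect_report <- function(n, icc, N = n) {
  deff <- design_effect(n, icc)
  out <- list(n = n, icc = icc, N = N, deff = deff,
              n_effective = effective_n(N, deff),
              se_underest_theory = se_underestimation_theoretical(n, icc),
              t_over_theory = t_overestimation_theoretical(n, icc),
              efficacy_loss = efficacy_loss(n, icc))
  class(out) <- "deff_report"
  out
}

#' @export
print.deff_report <- function(x, ...) {
  cat("Design-effect report\n")
  cat(sprintf("  cluster size n = %g, ICC = %.3f\n", x$n, x$icc))
  cat(sprintf("  Deff = %.3f; effective N = %.1f of %g\n",
              x$deff, x$n_effective, x$N))
  cat(sprintf("  SE underestimation (theory): %.2f%%\n",
              x$se_underest_theory))
  cat(sprintf("  t-score overestimation (theory): %.2f%%\n",
              x$t_over_theory))
  cat(sprintf("  efficacy loss: %.2f%%\n", x$efficacy_loss))
  invisible(x)
}
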