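#' Durbin-Watson statistic
#'
#' `d = sum((e_i - e_{i-1})^2, i >= 2) / sum(e_i^2)`, computed on
#' residuals in a fixed order. For clustered allometric data the order is
#' stand-blocked (all trees of a stand contiguous, dataset row order
#' within a stand), which is what turns between-stand shifts of the
#' residuals into first-order autocorrelation. `d` ranges between 0 and
#' 4; values near 2 indicate no autocorrelation, small values positive
#' autocorrelation.
#'
#' @param residuals Numeric residual vector in stand-then-tree order.
#' @return The Durbin-Watson statistic.
#' @examples
#' durbin_watson(c(1, -1, 1, -1))  # 3
#' durbin_watson(c(1, 2, 3))      # 2/14
#' @export
durbin_watson <- function(residuals) {
  e <- as.numeric(residuals)
  if (length(e) < 2) stop("need at least 2 residuals", call. = FALSE)
  den <- sum(e^2)
  if (den == 0) {
    stop("undefined statistic: all residuals are zero", call. = FALSE)
  }
  sum(diff(e)^2) / den
}

#' Critical bounds for the Durbin-Watson test
#'
#' Looks up the lower and upper critical values `(dL, dU)` of the
#' Durbin-Watson bounds test from an embedded table of published bounds
#' (one to five predictors, significance levels 1\% and 5\%), with linear
#' interpolation in `N` between tabulated sample sizes. Requests outside
#' the tabulated range raise an error rather than extrapolating.
#'
#' @param N Number of observations.
#' @param k Number of predictors (1 to 5, excluding the intercept).
#' @param alpha_level Significance level, `0.05` or `0.01`.
#' @return Named vector `c(dL, dU)`.
#' @examples
#' dw_critical_values(110, 1, 0.05)  # dL = 1.671, dU = 1.707
#' @export
dw_critical_values <- function(N, k = 1, alpha_level = 0.05) {
  if (!k %in% 1:5) {
    stop("out of range: `k` must be 1..5", call. = FALSE)
  }
  if (!alpha_level %in% c(0.01, 0.05)) {
    stop("out of range: `alpha_level` must be 0.01 or 0.05",
         call. = FALSE)
  }
  tab <- dw_bounds_table[dw_bounds_table$k == k &
                           dw_bounds_table$alpha == alpha_level, ]
  if (N < min(tab$N) || N > max(tab$N)) {
    stop("out of range: N = ", N, " outside tabulated range [",
         min(tab$N), ", ", max(tab$N), "] for k = ", k,
         ", alpha = ", alpha_level, call. = FALSE)
  }
  dL <- stats::approx(tab$N, tab$dL, xout = N)$y
  dU <- stats::approx(tab$N, tab$dU, xout = N)$y
  c(dL = dL, dU = dU)
}

#' Durbin-Watson bounds-test decision
#'
#' Applies the classic three-way decision rule: `d < dL` rejects the null
#' of zero autocorrelation in favour of positive autocorrelation;
#' `dL <= d <= dU` is inconclusive; `d > dU` accepts the null.
#'
#' @param d Durbin-Watson statistic.
#' @param dL,dU Lower and upper critical bounds (`dL < dU`).
#' @return One of `"positive_autocorrelation"`, `"inconclusive"`,
#'   `"no_autocorrelation"`.
#' @export
dw_decision <- function(d, dL, dU) {
  stopifnot(dL < dU)
  if (d < dL) "positive_autocorrelation"
  else if (d <= dU) "inconclusive"
  else "no_autocorrelation"
}

#' Naive ICC approximation from the Durbin-Watson statistic
#'
#' Assuming a linear mapping of the `d` interval of interest `[0, 2]`
#' onto the ICC interval `[1, 0]`, the intraclass correlation can be
#' roughly approximated as `ICC = 1 - 0.5 d`. For `d > 2` (negative
#' autocorrelation, not expected in clustered allometric data) the value
#' is clamped at 0.
#'
#' @param d Durbin-Watson statistic in `[0, 4]`.
#' @return Approximate ICC in `[0, 1]`.
#' @examples
#' icc_from_dw(1.671)  # 0.1645
#' @export
icc_from_dw <- function(d) {
  if (any(d < 0 | d > 4)) {
    stop("`d` must lie in [0, 4]", call. = FALSE)
  }
  pmax(0, 1 - 0.5 * d)
}

#' ICC detection limit of the Durbin-Watson test
#'
#' The approximate ICC below which the Durbin-Watson bounds test fails to
#' flag clustering: `icc_from_dw(dL)`, where `dL` is the lower critical
#' bound for the design. ICC values under this limit correspond to
#' `d > dL`, where the test is inconclusive or indicates no
#' autocorrelation. The limit decreases with `N`.
#'
#' @inheritParams dw_critical_values
#' @return The ICC detection bound.
#' @examples
#' dw_detection_bound(110, 1, 0.05)  # about 0.165
#' @export
dw_detection_bound <- function(N, k = 1, alpha_level = 0.05) {
  cv <- dw_critical_values(N, k, alpha_level)
  unname(icc_from_dw(cv["dL"]))
}

#' Durbin-Watson bounds test on a residual vector
#'
#' Computes the statistic, looks up the critical bounds, applies the
#' decision rule and attaches the naive ICC approximation.
#'
#' @param residuals Residuals in stand-then-tree order.
#' @param k Number of predictors of the model that produced them.
#' @param alpha_level Significance level (0.05 or 0.01).
#' @return Object of class `dw_result`: `d`, `dL`, `dU`, `alpha_level`,
#'   `decision`, `icc_approx`, `N`, `k`.
#' @export
dw_test <- function(residuals, k = 1, alpha_level = 0.05) {
  d <- durbin_watson(residuals)
  cv <- dw_critical_values(length(residuals), k, alpha_level)
  out <- list(d = d, dL = unname(cv["dL"]), dU = unname(cv["dU"]),
              alpha_level = alpha_level,
              decision = dw_decision(d, cv["dL"], cv["dU"]),
              icc_approx = icc_from_dw(min(d, 4)),
              N = length(residuals), k = k)
  class(out) <- "dw_result"
  out
}

#' @export
print.dw_result <- function(x, ...) {
  cat(sprintf("Durbin-Watson bounds test (N = %d, k = %d, alpha = %g)\n",
              x$N, x$k, x$alpha_level))
  cat(sprintf("  d = %.4f; bounds dL = %.3f, dU = %.3f\n",
              x$d, x$dL, x$dU))
  cat(sprintf("  decision: %s; naive ICC approximation: %.4f\n",
              x$decision, x$icc_approx))
  invisible(x)
}
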