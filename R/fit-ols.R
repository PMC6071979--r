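#' Ordinary least squares fit (independence assumed)
#'
#' Fits `y = alpha + beta' x + eps` by closed-form normal equations,
#' treating all observations as independent. In the allometric context
#' `x` and `y` are natural-log transformed diameter (or height) and
#' biomass, so `beta` is the allometric exponent and `exp(alpha)` the
#' scaling coefficient.
#'
#' @param x Numeric predictor vector, or a matrix with one column per
#'   predictor (no intercept column).
#' @param y Numeric response vector of the same length.
#' @return An object of class `ols_fit`: a list with `alpha_hat`,
#'   `beta_hat` (named vector for multiple predictors), `se_alpha`,
#'   `se_beta`, `t_alpha`, `t_beta`, `rse` (residual standard error),
#'   `residuals`, `df` (`N - p - 1`), `N`, and `coef`/`vcov` for the full
#'   coefficient vector.
#' @examples
#' f <- fit_ols(c(1, 2, 3), c(1, 2, 2))
#' f$beta_hat   # 0.5
#' f$alpha_hat  # 2/3
#' @export
fit_ols <- function(x, y) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) {
    colnames(X) <- if (ncol(X) == 1) "x" else paste0("x", seq_len(ncol(X)))
  }
  y <- as.numeric(y)
  N <- length(y)
  if (nrow(X) != N) stop("`x` and `y` lengths differ", call. = FALSE)
  p <- ncol(X)
  if (N < p + 2) stop("insufficient data: need at least p + 2 observations",
                      call. = FALSE)
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("singular design: constant predictor", call. = FALSE)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  XtX <- crossprod(Xd)
  Xty <- crossprod(Xd, y)
  R <- tryCatch(chol(XtX),
                error = function(e) stop("singular design", call. = FALSE))
  coef <- drop(backsolve(R, forwardsolve(t(R), Xty)))
  names(coef) <- colnames(Xd)
  res <- y - drop(Xd %*% coef)
  df <- N - p - 1
  rse <- sqrt(sum(res^2) / df)
  XtX_inv <- chol2inv(R)
  vcov <- rse^2 * XtX_inv
  dimnames(vcov) <- list(colnames(Xd), colnames(Xd))
  se <- sqrt(diag(vcov))
  out <- list(
    alpha_hat = unname(coef[1]),
    beta_hat = if (p == 1) unname(coef[2]) else coef[-1],
    se_alpha = unname(se[1]),
    se_beta = if (p == 1) unname(se[2]) else se[-1],
    t_alpha = unname(coef[1] / se[1]),
    t_beta = if (p == 1) unname(coef[2] / se[2]) else coef[-1] / se[-1],
    rse = rse,
    residuals = res,
    df = df,
    N = N,
    coef = coef,
    vcov = vcov
  )
  class(out) <- "ols_fit"
  out
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: N = %d, df = %d, RSE = %.5g\n", x$N, x$df, x$rse))
  tab <- data.frame(estimate = x$coef,
                    se = sqrt(diag(x$vcov)),
                    t = x$coef / sqrt(diag(x$vcov)))
  print(round(tab, 5))
  invisible(x)
}
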