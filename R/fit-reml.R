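# Random-intercept multilevel model, estimated by restricted maximum
# likelihood. The restricted likelihood is profiled over the variance
# ratio lambda = tau2 / sigma2: for any candidate lambda the marginal
# covariance is sigma2 * R with R = I + lambda * Z Z' block-diagonal over
# stands, so fixed effects, sigma2 and the restricted log-likelihood all
# have closed forms from per-stand sums, and a 1-D search over log(lambda)
# finds the optimum.

# Per-stand sufficient statistics; computing them once makes each
# profile-likelihood evaluation O(J p^2).
reml_precompute <- function(y, stand, X) {
  idx <- split(seq_along(y), stand)
  J <- length(idx)
  p <- ncol(X)
  nj <- lengths(idx)
  sx <- matrix(0, J, p)         # column sums of X per stand
  sy <- numeric(J)              # sum of y per stand
  Sxx <- array(0, c(p, p, J))   # X'X per stand
  sxy <- matrix(0, J, p)        # X'y per stand
  syy <- numeric(J)
  for (j in seq_len(J)) {
    Xi <- X[idx[[j]], , drop = FALSE]
    yi <- y[idx[[j]]]
    sx[j, ] <- colSums(Xi)
    sy[j] <- sum(yi)
    Sxx[, , j] <- crossprod(Xi)
    sxy[j, ] <- crossprod(Xi, yi)
    syy[j] <- sum(yi^2)
  }
  list(idx = idx, J = J, p = p, nj = nj, N = length(y),
       sx = sx, sy = sy,
       Sxx_tot = apply(Sxx, c(1, 2), sum),
       sxy_tot = colSums(sxy), syy_tot = sum(syy),
       stand_levels = names(idx))
}

# GLS solve and profiled restricted log-likelihood at a given lambda.
reml_eval <- function(lambda, pre) {
  w <- lambda / (1 + pre$nj * lambda)           # shrinkage weight per stand
  A <- pre$Sxx_tot - crossprod(pre$sx * w, pre$sx)
  cvec <- pre$sxy_tot - colSums(pre$sx * (w * pre$sy))
  yRy <- pre$syy_tot - sum(w * pre$sy^2)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    return(list(loglik = -Inf, coef = rep(NA_real_, pre$p),
                sigma2 = NA_real_, A = A))
  }
  b <- drop(backsolve(R, forwardsolve(t(R), cvec)))
  rRr <- max(yRy - sum(b * cvec), 0)
  dfres <- pre$N - pre$p
  sigma2 <- rRr / dfres
  logdetR <- sum(log1p(pre$nj * lambda))
  logdetA <- 2 * sum(log(diag(R)))
  loglik <- if (sigma2 <= 0) Inf else {
    -0.5 * (dfres * log(2 * pi) + dfres * log(sigma2) +
              logdetR + logdetA + dfres)
  }
  list(loglik = loglik, coef = b, sigma2 = sigma2, A = A, chol_A = R,
       rRr = rRr)
}

#' Profiled restricted log-likelihood of the random-intercept model
#'
#' Evaluates the restricted log-likelihood of the model
#' `y_ij = alpha + u_j + beta' x_ij + eps_ij` at a candidate variance
#' ratio `lambda = tau2 / sigma2`, with the residual variance profiled
#' out (`sigma2` set to its closed-form REML value at that `lambda`).
#' Exposed so the optimum found by [fit_random_intercept_reml()] can be
#' checked against a brute-force grid.
#'
#' @param lambda Non-negative variance ratio `tau2 / sigma2`.
#' @param y Numeric response.
#' @param stand_ids Cluster labels, one per observation.
#' @param x Optional predictor vector or matrix.
#' @return The restricted log-likelihood (a scalar; `-Inf` for singular
#'   designs).
#' @export
reml_profile_loglik <- function(lambda, y, stand_ids, x = NULL) {
  y <- as.numeric(y)
  X <- if (is.null(x)) matrix(1, length(y), 1) else cbind(1, as.matrix(x))
  pre <- reml_precompute(y, as.character(stand_ids), X)
  vapply(lambda, function(l) reml_eval(l, pre)$loglik, numeric(1))
}

#' Fit a random-intercept multilevel model by REML
#'
#' Fits `y_ij = alpha + u_j + beta' x_ij + eps_ij` with stand effects
#' `u_j ~ N(0, tau2)` and residuals `eps_ij ~ N(0, sigma2)`, by restricted
#' maximum likelihood. The restricted likelihood is profiled over the
#' variance ratio `tau2 / sigma2` (closed-form generalized least squares
#' at each candidate, 1-D optimization on the log ratio), and `tau2` is
#' truncated at zero when the optimum lies on the boundary. With `x`
#' omitted the intercept-only variance-components model is fitted.
#'
#' Fixed-effect standard errors come from the GLS information at the
#' optimum. t-scores and confidence intervals use between-within degrees
#' of freedom: `J - 1` for the intercept (a stand-level quantity) and
#' `N - J - p` for the `p` covariates.
#'
#' @param y Numeric response (log biomass).
#' @param stand_ids Cluster labels, one per observation; at least two
#'   distinct stands.
#' @param x Optional predictor vector or matrix (log diameter/height).
#' @return An object of class `mlm_fit`: `alpha_hat` (population
#'   intercept from which stand intercepts `alpha_hat + u[j]` deviate),
#'   `beta_hat`, `se_alpha`, `se_beta`, `t_alpha`, `t_beta`, `df_alpha`,
#'   `df_beta`, variance components `tau2`, `sigma2`, `icc`, stand
#'   predictions `u` (BLUPs), `J`, `N`, `converged`, `boundary` (`TRUE`
#'   when `tau2` was truncated at zero), `loglik` (restricted),
#'   `residuals` (conditional, i.e. `y - alpha - u_j - beta x`),
#'   `marginal_residuals`, `coef`, `vcov`.
#' @examples
#' f <- fit_random_intercept_reml(c(0, 2, 4, 6), c("A", "A", "B", "B"))
#' c(f$sigma2, f$tau2, f$icc)  # 2, 7, 7/9
#' @export
fit_random_intercept_reml <- function(y, stand_ids, x = NULL) {
  y <- as.numeric(y)
  stand <- as.character(stand_ids)
  N <- length(y)
  if (length(stand) != N) stop("`stand_ids` length mismatch", call. = FALSE)
  if (N < 3) stop("insufficient data: need at least 3 observations",
                  call. = FALSE)
  J <- length(unique(stand))
  if (J < 2) {
    stop("no between-stand variance estimable from a single stand",
         call. = FALSE)
  }
  X <- if (is.null(x)) {
    matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xm <- as.matrix(x)
    if (any(apply(Xm, 2, stats::sd) == 0)) {
      stop("singular design: constant predictor", call. = FALSE)
    }
    if (is.null(colnames(Xm))) {
      colnames(Xm) <- if (ncol(Xm) == 1) "x" else
        paste0("x", seq_len(ncol(Xm)))
    }
    cbind(`(Intercept)` = 1, Xm)
  }
  p <- ncol(X)

  # degenerate all-equal response: no variance at either level
  if (stats::var(y) == 0) {
    warning("response has zero variance; returning tau2 = sigma2 = 0")
    coef <- c(y[1], rep(0, p - 1))
    names(coef) <- colnames(X)
    u <- stats::setNames(rep(0, J), sort(unique(stand)))
    out <- list(alpha_hat = y[1],
                beta_hat = if (p > 1) coef[-1] else NULL,
                se_alpha = 0, se_beta = if (p > 1) rep(0, p - 1) else NULL,
                t_alpha = NA_real_, t_beta = NULL,
                df_alpha = J - 1, df_beta = N - J - (p - 1),
                tau2 = 0, sigma2 = 0, icc = 0, u = u, J = J, N = N,
                converged = TRUE, boundary = TRUE, lambda = 0,
                loglik = NA_real_, residuals = rep(0, N),
                marginal_residuals = rep(0, N), coef = coef,
                vcov = matrix(0, p, p, dimnames = list(colnames(X),
                                                       colnames(X))))
    class(out) <- "mlm_fit"
    return(out)
  }

  pre <- reml_precompute(y, stand, X)
  obj <- function(loglam) reml_eval(exp(loglam), pre)$loglik
  opt <- stats::optimize(obj, interval = log(c(1e-10, 1e10)),
                         maximum = TRUE, tol = 1e-10)
  lambda <- exp(opt$maximum)
  ll_hat <- opt$objective
  ll_zero <- reml_eval(0, pre)$loglik
  boundary <- FALSE
  if (lambda < 1e-7 || ll_zero >= ll_hat) {
    lambda <- 0
    boundary <- TRUE
  }
  fit <- reml_eval(lambda, pre)
  converged <- is.finite(fit$loglik) && all(is.finite(fit$coef))
  sigma2 <- fit$sigma2
  tau2 <- lambda * sigma2
  icc <- if (tau2 + sigma2 > 0) tau2 / (tau2 + sigma2) else 0

  coef <- stats::setNames(fit$coef, colnames(X))
  vcov <- sigma2 * chol2inv(fit$chol_A)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))

  marg <- y - drop(X %*% coef)
  # BLUP of the stand effect: shrunken stand mean of marginal residuals
  msum <- tapply(marg, stand, sum)
  nj <- pre$nj[names(msum)]
  u <- (lambda / (1 + nj * lambda)) * as.numeric(msum)
  names(u) <- names(msum)
  cond <- marg - u[stand]

  out <- list(
    alpha_hat = unname(coef[1]),
    beta_hat = if (p > 2) coef[-1] else if (p == 2) unname(coef[2]) else
      NULL,
    se_alpha = unname(se[1]),
    se_beta = if (p > 2) se[-1] else if (p == 2) unname(se[2]) else NULL,
    t_alpha = unname(coef[1] / se[1]),
    t_beta = if (p > 2) coef[-1] / se[-1] else if (p == 2)
      unname(coef[2] / se[2]) else NULL,
    df_alpha = J - 1,
    df_beta = N - J - (p - 1),
    tau2 = tau2, sigma2 = sigma2, icc = icc,
    u = u, J = J, N = N,
    converged = converged, boundary = boundary,
    lambda = lambda, loglik = fit$loglik,
    residuals = as.numeric(cond),
    marginal_residuals = as.numeric(marg),
    coef = coef, vcov = vcov
  )
  class(out) <- "mlm_fit"
  out
}

#' Balanced one-way ANOVA variance components
#'
#' Closed-form method-of-moments estimator for the intercept-only
#' random-effects model on a balanced design: `sigma2 = MSW` (within-stand
#' mean square) and `tau2 = max(0, (MSB - MSW) / n)`. For balanced designs
#' with interior solutions these equal the REML estimates, which makes
#' this the independent oracle for [fit_random_intercept_reml()].
#'
#' @param y Numeric response.
#' @param stand_ids Cluster labels; every stand must have the same number
#'   of observations.
#' @return List with `sigma2`, `tau2`, `msw`, `msb`, `n` (common cluster
#'   size) and `boundary` (`TRUE` when the moment estimate of `tau2` was
#'   negative and truncated).
#' @examples
#' anova_variance_components(c(0, 2, 4, 6), c("A", "A", "B", "B"))
#' @export
anova_variance_components <- function(y, stand_ids) {
  y <- as.numeric(y)
  stand <- as.character(stand_ids)
  sizes <- table(stand)
  if (length(unique(as.integer(sizes))) != 1L) {
    stop("unsupported design: ANOVA variance components require a ",
         "balanced design", call. = FALSE)
  }
  n <- as.integer(sizes[1])
  J <- length(sizes)
  if (J < 2 || n < 1) stop("need >= 2 stands", call. = FALSE)
  if (stats::var(y) == 0) {
    warning("response has zero variance; returning tau2 = sigma2 = 0")
    return(list(sigma2 = 0, tau2 = 0, msw = 0, msb = 0, n = n,
                boundary = TRUE))
  }
  gm <- mean(y)
  means <- tapply(y, stand, mean)
  ssb <- n * sum((means - gm)^2)
  ssw <- sum((y - means[stand])^2)
  msb <- ssb / (J - 1)
  msw <- if (n > 1) ssw / (J * (n - 1)) else 0
  tau2_raw <- (msb - msw) / n
  list(sigma2 = msw, tau2 = max(0, tau2_raw), msw = msw, msb = msb,
       n = n, boundary = tau2_raw < 0)
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept model (REML): N = %d trees, J = %d stands\n",
              x$N, x$J))
  cat(sprintf("  tau2 = %.5g, sigma2 = %.5g, ICC = %.4f%s\n",
              x$tau2, x$sigma2, x$icc,
              if (x$boundary) " (tau2 at boundary)" else ""))
  tab <- data.frame(estimate = x$coef,
                    se = sqrt(diag(x$vcov)))
  tab$t <- tab$estimate / tab$se
  print(round(tab, 5))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}
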