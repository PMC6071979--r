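#' Type-I-error inflation experiment
#'
#' Measures the rejection rate of a true null hypothesis when clustering
#' is ignored. Each replicate simulates a clustered biomass dataset and a
#' second continuous covariate `z` with true slope zero that varies
#' mostly *between* stands (the stand-level scenario of, e.g., site or
#' crown variables): `z_ij = z_j + w_ij` with `z_j ~ N(0, between_sd^2)`
#' and `w_ij ~ N(0, within_sd^2)`. Both models are then fitted with
#' `ln(D)` and `z` as covariates, and the slope of `z` is t-tested at the
#' requested level — OLS with `N - 3` degrees of freedom, the multilevel
#' model with its between-within degrees of freedom.
#'
#' With independent data (ICC = 0) both rates should sit near the nominal
#' level; with clustered data the OLS rate inflates roughly with the
#' design effect of `z`, while the multilevel rate should stay near
#' nominal.
#'
#' @param icc Target intraclass correlation of the simulated biomass.
#' @param n Trees per stand.
#' @param J Number of stands.
#' @param replicates Number of Monte-Carlo replicates (>= 100).
#' @param seed Master seed.
#' @param level Test level (default 0.05).
#' @param z_between_sd,z_within_sd Between- and within-stand SD of the
#'   null covariate; the default mixing makes it predominantly a
#'   stand-level variable.
#' @param sigma2 Within-stand residual variance of log biomass.
#' @return List: `rate_lm`, `rate_mlm` (rejection rates), `replicates`,
#'   `n_failed` (fit failures, excluded from the rates and reported),
#'   `icc`, `n`, `J`, `level`, `seed`.
#' @examples
#' \donttest{
#' type1_error_experiment(icc = 0.5, n = 10, J = 22, replicates = 200,
#'                        seed = 7)
#' }
#' @export
type1_error_experiment <- function(icc, n, J = 22, replicates = 1000L,
                                   seed = 1L, level = 0.05,
                                   z_between_sd = 1, z_within_sd = 0.25,
                                   sigma2 = 0.02) {
  if (replicates < 100) {
    stop("`replicates` must be >= 100 for a stable rate", call. = FALSE)
  }
  rej_lm <- rej_mlm <- logical(replicates)
  failed <- 0L
  for (r in seq_len(replicates)) {
    rs <- derive_seed(seed, r)
    cfg <- sim_config(J = J, n = n, tau2 = tau2_for_icc(icc, sigma2),
                      sigma2 = sigma2, seed = rs)
    dat <- generate_dataset(cfg)
    set.seed(derive_seed(rs, 1L))
    zj <- stats::rnorm(J, 0, z_between_sd)
    stand_index <- match(dat$stand_id, unique(dat$stand_id))
    z <- zj[stand_index] + stats::rnorm(nrow(dat), 0, z_within_sd)
    y <- log(dat$TB_g)
    X <- cbind(logD = log(dat$D_mm), z = z)
    res <- tryCatch({
      ols <- fit_ols(X, y)
      mlm <- fit_random_intercept_reml(y, dat$stand_id, X)
      t_lm <- unname(ols$t_beta["z"])
      t_mlm <- unname(mlm$t_beta["z"])
      c(lm = abs(t_lm) > stats::qt(1 - level / 2, ols$df),
        mlm = abs(t_mlm) > stats::qt(1 - level / 2, mlm$df_beta))
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      rej_lm[r] <- NA
      rej_mlm[r] <- NA
    } else {
      rej_lm[r] <- res["lm"]
      rej_mlm[r] <- res["mlm"]
    }
  }
  list(rate_lm = mean(rej_lm, na.rm = TRUE),
       rate_mlm = mean(rej_mlm, na.rm = TRUE),
       replicates = replicates, n_failed = failed,
       icc = icc, n = n, J = J, level = level, seed = seed)
}
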