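#' Render study artifacts to a directory
#'
#' Writes the machine-readable outputs of a validation study: per-cell
#' observed-versus-theoretical tables, the ICC-versus-d records,
#' theoretical curve data (standard-error underestimation, t-score
#' overestimation, Durbin-Watson ICC detection bounds, efficacy loss), a
#' JSON summary and a log of seeds and versions. Every number is computed
#' by the package's own operations; the renderer only tabulates.
#'
#' @param study A `study_result` from [run_validation_study()].
#' @param outdir Output directory (created if missing).
#' @param detection_N Sample sizes for the detection-bound export.
#' @param efficacy_iccs ICC values for the efficacy-loss export.
#' @param efficacy_n_max Largest cluster size for the efficacy-loss
#'   export.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(study, outdir,
                          detection_N = seq(20, 200, by = 5),
                          efficacy_iccs = c(0, 0.01, 0.1, 0.5, 0.8),
                          efficacy_n_max = 30) {
  stopifnot(inherits(study, "study_result"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) {
      stop("cannot create output directory: ", outdir, call. = FALSE)
    }
  }
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  wr(study$cells, "observed_vs_theoretical.csv")
  wr(study$icc_vs_d$data, "icc_vs_d.csv")
  if (!is.null(study$type1)) wr(study$type1, "type1_error.csv")

  icc_grid <- seq(0, 1, by = 0.01)
  ns <- sort(unique(study$cells$n))
  curves <- do.call(rbind, lapply(ns, function(n) {
    data.frame(n = n, icc = icc_grid,
               seu_theory = se_underestimation_theoretical(n, icc_grid),
               t_ovr_theory = t_overestimation_theoretical(n, icc_grid))
  }))
  wr(curves, "theoretical_curves.csv")

  bounds <- do.call(rbind, lapply(c(0.05, 0.01), function(a) {
    data.frame(alpha = a, N = detection_N, k = 1,
               icc_bound = vapply(detection_N, dw_detection_bound,
                                  numeric(1), k = 1, alpha_level = a))
  }))
  wr(bounds, "dw_detection_bounds.csv")

  eff <- do.call(rbind, lapply(efficacy_iccs, function(icc) {
    n <- seq_len(efficacy_n_max)
    data.frame(icc = icc, n = n, efficacy_loss = efficacy_loss(n, icc))
  }))
  wr(eff, "efficacy_loss_curves.csv")

  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summary <- list(
      seed = study$seed, J = study$J, replicates = study$replicates,
      cells = study$cells,
      icc_vs_d = list(intercept = study$icc_vs_d$intercept,
                      slope = study$icc_vs_d$slope,
                      ci_intercept = study$icc_vs_d$ci_intercept,
                      ci_slope = study$icc_vs_d$ci_slope,
                      p_intercept_eq_1 = study$icc_vs_d$p_intercept_eq_1,
                      p_slope_eq_minus_0.5 =
                        study$icc_vs_d$p_slope_eq_minus_0.5),
      mean_icc_test = list(
        estimate = unname(study$mean_icc_test$estimate),
        statistic = unname(study$mean_icc_test$statistic),
        p_value = study$mean_icc_test$p.value)
    )
    if (!is.null(study$type1)) summary$type1 <- study$type1
    path <- file.path(outdir, "summary.json")
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, path)
  }

  log_path <- file.path(outdir, "log.txt")
  writeLines(c(
    sprintf("allocluster %s", as.character(utils::packageVersion("allocluster"))),
    sprintf("R %s", getRversion()),
    sprintf("master seed: %d", study$seed),
    sprintf("cell seeds: %s", paste(study$cells$seed, collapse = ", ")),
    sprintf("icc_vs_d seed: %d", study$icc_vs_d$seed),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  ), log_path)
  files <- c(files, log_path)
  invisible(files)
}
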