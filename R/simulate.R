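#' Default biomass-component parameters
#'
#' Component-level power-law parameters used when component generation is
#' enabled: stem (ST), branches (BR), needles (ND) and roots (RT) each get
#' their own log-scale intercept, allometric exponent and residual variance,
#' while sharing the stand-level random intercept with total biomass.
#' Defaults give roughly 50/20/15/15 percent biomass shares for a tree of
#' 60 mm root collar diameter. Residual variances are component-specific,
#' reflecting how tightly each component tracks diameter in practice: stem
#' biomass is predicted tightly, roots moderately, branches and needles
#' noisily — which also spreads the implied per-component intraclass
#' correlations over a wide range for a common between-stand variance.
#' Each component also carries its own stand-level deviation on top of
#' the shared stand effect (`tau2_extra`): stands differ not only in
#' overall productivity but in how they allocate biomass among stem,
#' branches, needles and roots, so the stand effects of the four
#' components are positively correlated but not identical.
#'
#' @return A data frame with columns `component`, `alpha`, `beta`,
#'   `sigma2`, `tau2_extra`.
#' @export
default_component_params <- function() {
  data.frame(
    component = c("ST", "BR", "ND", "RT"),
    alpha = c(-3.60, -3.69, -3.16, -4.39),
    beta = c(2.50, 2.30, 2.10, 2.40),
    sigma2 = c(0.005, 0.08, 0.15, 0.04),
    tau2_extra = c(0.01, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for clustered allometric data
#'
#' Defines the data-generating process for a stand-nested tree biomass
#' sample: `J` forest stands with `n` trees each, a power-law
#' biomass-diameter relation with multiplicative lognormal error, and a
#' stand-level random intercept that induces a target intraclass
#' correlation ICC = `tau2 / (tau2 + sigma2)`.
#'
#' Diameters are lognormal: stand mean log diameters are drawn with spread
#' `diameter_between_sd` and trees jitter around their stand mean with
#' `diameter_within_sd`. The default within-stand spread is very narrow
#' (coefficient of variation about 1\%), emulating deliberate sampling of
#' trees matching the stand's average size, while the between-stand spread
#' covers about one order of magnitude of diameter. The narrow within-stand
#' spread matters: it keeps the share of slope information carried by
#' within-stand diameter contrasts negligible, which is the regime in which
#' the design-effect theory for the slope applies exactly.
#'
#' @param J Number of stands (integer >= 1).
#' @param n Trees per stand (integer >= 1).
#' @param alpha Log-scale intercept of the total-biomass allometry
#'   (log grams at 1 mm diameter).
#' @param beta Allometric exponent (dimensionless).
#' @param tau2 Between-stand variance of log biomass (log-units squared,
#'   >= 0).
#' @param sigma2 Within-stand residual variance of log biomass (log-units
#'   squared, > 0).
#' @param diameter_mu Mean of log stand-mean root collar diameter (log mm).
#' @param diameter_between_sd SD of log stand-mean diameter across stands.
#' @param diameter_within_sd SD of log diameter within a stand; should be
#'   smaller than `diameter_between_sd` to reproduce the narrow
#'   within-stand size range of near-average-tree sampling.
#' @param height_params List with elements `alpha`, `beta`, `between_sd`,
#'   `within_sd`: height (cm) is generated from diameter through a
#'   stand-level allometric relation
#'   `log H = alpha + beta * log D + v_j + e_ij` with stand effects
#'   `v_j ~ N(0, between_sd^2)` and tree noise `e_ij ~ N(0, within_sd^2)`.
#'   Height deviations are dominated by the stand level (site quality);
#'   the tree-level noise is kept small so that, among near-average-size
#'   trees, height remains a usable predictor (a common-slope model on
#'   `log H` stays well specified).
#' @param components Logical; if `TRUE`, generate the four biomass
#'   components (ST, BR, ND, RT) from `component_params`, all sharing the
#'   stand effect `u_j`, and set total biomass TB to their exact sum. If
#'   `FALSE` (default), only TB is generated, exactly following the
#'   random-intercept log-linear model.
#' @param component_params Data frame as returned by
#'   [default_component_params()].
#' @param seed Integer RNG seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_dataset()]
#' @examples
#' cfg <- sim_config(J = 22, n = 10, tau2 = 0.02, sigma2 = 0.02, seed = 1)
#' implied_icc(cfg)
#' @export
sim_config <- function(J = 22, n = 10,
                       alpha = -2.5, beta = 2.4,
                       tau2 = 0.02, sigma2 = 0.02,
                       diameter_mu = log(60),
                       diameter_between_sd = 0.55,
                       diameter_within_sd = 0.01,
                       height_params = list(alpha = 2.45, beta = 0.75,
                                            between_sd = 0.06,
                                            within_sd = 0.005),
                       components = FALSE,
                       component_params = default_component_params(),
                       seed = 1L) {
  if (!is.numeric(J) || length(J) != 1 || is.na(J) || J < 1 ||
      J != round(J)) {
    stop("invalid config: `J` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 ||
      n != round(n)) {
    stop("invalid config: `n` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(tau2) || length(tau2) != 1 || is.na(tau2) || tau2 < 0) {
    stop("invalid config: `tau2` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1 || is.na(sigma2) ||
      sigma2 <= 0) {
    stop("invalid config: `sigma2` must be > 0", call. = FALSE)
  }
  for (nm in c("diameter_between_sd", "diameter_within_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop("invalid config: `", nm, "` must be >= 0", call. = FALSE)
    }
  }
  stopifnot(is.list(height_params),
            all(c("alpha", "beta", "between_sd", "within_sd") %in%
                  names(height_params)))
  if (isTRUE(components)) {
    stopifnot(is.data.frame(component_params),
              all(c("component", "alpha", "beta", "sigma2",
                    "tau2_extra") %in% names(component_params)),
              all(component_params$sigma2 > 0),
              all(component_params$tau2_extra >= 0))
  }
  cfg <- list(J = as.integer(J), n = as.integer(n),
              alpha = alpha, beta = beta, tau2 = tau2, sigma2 = sigma2,
              diameter_mu = diameter_mu,
              diameter_between_sd = diameter_between_sd,
              diameter_within_sd = diameter_within_sd,
              height_params = height_params,
              components = isTRUE(components),
              component_params = component_params,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Intraclass correlation implied by a configuration
#'
#' @param config A [sim_config()] object.
#' @return `tau2 / (tau2 + sigma2)`, in `[0, 1)`.
#' @export
implied_icc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$tau2 / (config$tau2 + config$sigma2)
}

#' Between-stand variance for a target ICC
#'
#' Convenience inverse of the ICC definition: returns the `tau2` that,
#' together with `sigma2`, yields the requested intraclass correlation.
#'
#' @param icc Target ICC in `[0, 1)`.
#' @param sigma2 Within-stand residual variance.
#' @return `icc / (1 - icc) * sigma2`.
#' @export
tau2_for_icc <- function(icc, sigma2 = 0.02) {
  if (any(icc < 0 | icc >= 1)) {
    stop("`icc` must lie in [0, 1)", call. = FALSE)
  }
  icc / (1 - icc) * sigma2
}

#' Generate a clustered allometric dataset
#'
#' Simulates `J * n` trees nested in `J` stands. On the natural-log scale
#' total biomass follows the random-intercept model
#' `log(TB_ij) = alpha + u_j + beta * log(D_ij) + eps_ij` with stand
#' effects `u_j ~ N(0, tau2)` drawn once per stand and tree-level errors
#' `eps_ij ~ N(0, sigma2)`. When `config$components` is `TRUE`, the four
#' biomass components are generated from their own power laws — sharing
#' the stand effect `u_j` but each adding its own stand-level allocation
#' deviation (`tau2_extra`) — and TB is their exact sum, in which case
#' the log-linear model for TB itself is only approximate.
#'
#' The output is deterministic given `config$seed`: stand-level draws
#' (diameter means, stand effects) are made first, then tree-level draws,
#' in a fixed order.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `alloc_data` with columns `stand_id`,
#'   `tree_id`, `D_mm`, `H_cm`, `ST_g`, `BR_g`, `ND_g`, `RT_g`, `TB_g`
#'   (component columns are `NA` unless component generation is enabled)
#'   and a `provenance` attribute of `"simulated"`.
#' @examples
#' d <- generate_dataset(sim_config(J = 5, n = 4, seed = 42))
#' nrow(d)   # 20
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a `sim_config` object", call. = FALSE)
  }
  J <- config$J
  n <- config$n
  N <- J * n
  set.seed(config$seed)

  # stand-level draws first (fixed order), then tree-level draws
  mu_logD <- stats::rnorm(J, config$diameter_mu, config$diameter_between_sd)
  u <- stats::rnorm(J, 0, sqrt(config$tau2))
  hp <- config$height_params
  v <- stats::rnorm(J, 0, hp$between_sd)

  stand <- rep(seq_len(J), each = n)
  logD <- stats::rnorm(N, mu_logD[stand], config$diameter_within_sd)
  logH <- hp$alpha + hp$beta * logD + v[stand] +
    stats::rnorm(N, 0, hp$within_sd)

  out <- data.frame(
    stand_id = sprintf("S%02d", stand),
    tree_id = rep(seq_len(n), times = J),
    D_mm = exp(logD),
    H_cm = exp(logH),
    ST_g = NA_real_, BR_g = NA_real_, ND_g = NA_real_, RT_g = NA_real_,
    TB_g = NA_real_,
    stringsAsFactors = FALSE
  )

  if (config$components) {
    cp <- config$component_params
    comp <- matrix(NA_real_, nrow = N, ncol = nrow(cp))
    for (k in seq_len(nrow(cp))) {
      u_extra <- stats::rnorm(J, 0, sqrt(cp$tau2_extra[k]))
      logW <- cp$alpha[k] + u[stand] + u_extra[stand] +
        cp$beta[k] * logD + stats::rnorm(N, 0, sqrt(cp$sigma2[k]))
      comp[, k] <- exp(logW)
    }
    colnames(comp) <- paste0(cp$component, "_g")
    out[, colnames(comp)] <- comp
    out$TB_g <- rowSums(comp)
  } else {
    logTB <- config$alpha + u[stand] + config$beta * logD +
      stats::rnorm(N, 0, sqrt(config$sigma2))
    out$TB_g <- exp(logTB)
  }

  as_alloc_data(out, provenance = "simulated")
}

#' Construct / validate a clustered allometry table
#'
#' Validates a tree-level table (stand labels, diameter, height, biomass)
#' and attaches the `alloc_data` class. Measurement columns must be
#' strictly positive so natural-log transforms are defined; violations are
#' reported with the offending row numbers.
#'
#' @param x Data frame with at least `stand_id`, `D_mm` and one biomass
#'   column among `ST_g`, `BR_g`, `ND_g`, `RT_g`, `TB_g`.
#' @param provenance Free-text origin tag, e.g. `"simulated"` or `"file"`.
#' @return `x` with classes `c("alloc_data", "data.frame")` and attributes
#'   `provenance` and `balanced` (`TRUE` iff all stands have equal tree
#'   counts).
#' @export
as_alloc_data <- function(x, provenance = "file") {
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"stand_id" %in% names(x)) {
    stop("validation error: missing mandatory column `stand_id`",
         call. = FALSE)
  }
  if (!"D_mm" %in% names(x)) {
    stop("validation error: missing mandatory column `D_mm`",
         call. = FALSE)
  }
  resp <- intersect(c("ST_g", "BR_g", "ND_g", "RT_g", "TB_g"), names(x))
  if (length(resp) == 0) {
    stop("validation error: need at least one response column ",
         "(ST_g, BR_g, ND_g, RT_g or TB_g)", call. = FALSE)
  }
  if (!"tree_id" %in% names(x)) {
    x$tree_id <- stats::ave(seq_len(nrow(x)), x$stand_id,
                            FUN = seq_along)
  }
  meas <- intersect(c("D_mm", "H_cm", resp), names(x))
  for (col in meas) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      stop("validation error: column `", col, "` is not numeric",
           call. = FALSE)
    }
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      stop("validation error: non-positive values in `", col,
           "` at rows ", paste(utils::head(bad, 10), collapse = ", "),
           call. = FALSE)
    }
  }
  sizes <- table(x$stand_id)
  structure(x,
            class = c("alloc_data", "data.frame"),
            provenance = provenance,
            balanced = length(unique(as.integer(sizes))) == 1L)
}

#' Cluster sizes of a dataset
#'
#' @param data An `alloc_data` data frame.
#' @return Named integer vector of trees per stand.
#' @export
cluster_sizes <- function(data) {
  stopifnot("stand_id" %in% names(data))
  tab <- table(data$stand_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Is the design balanced?
#'
#' @param data An `alloc_data` data frame.
#' @return `TRUE` iff every stand has the same number of trees.
#' @export
is_balanced <- function(data) {
  length(unique(cluster_sizes(data))) == 1L
}

#' Randomly subsample trees within every stand
#'
#' Selects `m` trees per stand uniformly without replacement, leaving the
#' stand set unchanged — the within-stand random subsampling used to build
#' a smaller-cluster-size dataset from a larger one.
#'
#' @param data An `alloc_data` data frame.
#' @param m Trees to keep per stand (every stand must have at least `m`).
#' @param seed Integer RNG seed; the subsample is deterministic given the
#'   seed.
#' @return An `alloc_data` data frame with `m` rows per stand, ordered by
#'   stand then tree.
#' @examples
#' d <- generate_dataset(sim_config(J = 22, n = 10, seed = 1))
#' nrow(subsample_clusters(d, m = 5, seed = 2))  # 110
#' @export
subsample_clusters <- function(data, m, seed = 1L) {
  stopifnot(inherits(data, "data.frame"), "stand_id" %in% names(data))
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  sizes <- cluster_sizes(data)
  short <- names(sizes)[sizes < m]
  if (length(short) > 0) {
    stop("insufficient cluster size: stands with fewer than ", m,
         " trees: ", paste(short, collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  stands <- unique(data$stand_id)
  keep <- integer(0)
  for (s in stands) {
    idx <- which(data$stand_id == s)
    keep <- c(keep, sort(sample(idx, m)))
  }
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_alloc_data(out, provenance = attr(data, "provenance") %||% "file")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_config <- function(x, ...) {
  cat("Clustered allometry simulation config\n")
  cat(sprintf("  stands J = %d, trees per stand n = %d (N = %d)\n",
              x$J, x$n, x$J * x$n))
  cat(sprintf("  log TB = %.3f + u_j + %.3f log D + eps\n",
              x$alpha, x$beta))
  cat(sprintf("  tau2 = %.4g, sigma2 = %.4g  (ICC = %.3f)\n",
              x$tau2, x$sigma2, implied_icc(x)))
  cat(sprintf("  components: %s, seed: %d\n",
              if (x$components) "ST+BR+ND+RT (TB = sum)" else "TB only",
              x$seed))
  invisible(x)
}

#' @export
print.alloc_data <- function(x, ...) {
  cat(sprintf("Clustered allometry dataset: %d trees in %d stands (%s%s)\n",
              nrow(x), length(unique(x$stand_id)),
              attr(x, "provenance") %||% "unknown",
              if (isTRUE(attr(x, "balanced"))) ", balanced" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
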