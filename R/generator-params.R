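#' Ground-truth parameters for the synthetic detachment experiment
#'
#' Returns the full set of generator coefficients and covariate
#' distributions the synthetic study is drawn from.  Defaults are
#' calibrated against the published per-condition summaries of the
#' porcine tongue-detachment experiment (four cells: tongue region apex /
#' basis crossed with gradual / rapid release) and its headline fitted
#' effects: a quadratic metal-temperature effect on peak detachment force
#' maximal at -7.5 degC, a per-SD force log-odds of 1.44 for avulsion
#' injury, and marginal injury rates of about 54\% (avulsion) and 92\%
#' (cold injury).
#'
#' The per-cell covariate table draws application and detachment times
#' from gamma distributions (strictly positive, matching each cell's mean
#' and SD) and metal temperature from a normal truncated to
#' [-40, +2] degC.  Contact time is the sum of application and detachment
#' time, mirroring the stage decomposition of the force-time traces.
#'
#' @param ... named overrides for any parameter, e.g.
#'   `generator_params(gamma1 = 0)`.  Unknown names are an error.
#'
#' @return An object of class `tt_generator_params`: a named list with
#'   components
#'   \describe{
#'     \item{covariates}{data frame of per-cell distribution parameters
#'       (means and SDs for application time, detachment time, metal
#'       temperature, tongue weight, tongue temperature).}
#'     \item{cell_mean_force}{named vector, expected peak force (N) per
#'       region x release cell at the cell's covariate means.}
#'     \item{beta_contact}{force slope on contact time, N/s.}
#'     \item{kappa, T_peak}{curvature (N/degC^2) and location (degC) of
#'       the quadratic metal-temperature effect
#'       q(T) = -kappa (T - T_peak)^2.}
#'     \item{sigma_batch, sigma_tongue, sigma_resid}{force random-effect
#'       and residual SDs (N).}
#'     \item{gamma0, gamma1, sigma_avulsion_re}{avulsion logistic
#'       intercept, slope per SD of force, and tongue random-intercept SD.}
#'     \item{delta0, delta1}{cold-injury logistic intercept and per-degC
#'       metal-temperature slope.}
#'     \item{metal_temp_range}{truncation bounds for metal temperature.}
#'     \item{p_poor_quality_apex}{probability of a pre-existing
#'       poor-quality apex surface.}
#'   }
#' @examples
#' p <- generator_params()
#' p$cell_mean_force
#' generator_params(gamma1 = 0)$gamma1
#' @export
generator_params <- function(...) {
  covariates <- data.frame(
    region  = rep(c("apex", "basis"), each = 2L),
    release = rep(c("gradual", "rapid"), 2L),
    application_mean = c(3.8, 3.7, 4.2, 4.1),
    application_sd   = c(1.8, 1.9, 1.8, 1.9),
    detachment_mean  = c(3.9, 2.3, 3.6, 1.6),
    detachment_sd    = c(1.5, 1.9, 1.8, 1.4),
    metal_temp_mean  = c(-13.8, -13.5, -15.0, -12.1),
    metal_temp_sd    = c(8.1, 7.9, 8.6, 7.9),
    stringsAsFactors = FALSE
  )
  params <- list(
    covariates = covariates,
    tongue_weight_mean = 196.2, tongue_weight_sd = 25.9,
    tongue_temp_mean = 34.65, tongue_temp_sd = 1.9,
    cell_mean_force = c(
      apex.gradual = 10.9, apex.rapid = 16.4,
      basis.gradual = 13.0, basis.rapid = 22.6
    ),
    beta_contact = 1.0,
    kappa = 0.008,
    T_peak = -7.5,
    sigma_batch = 1.5,
    sigma_tongue = 3.0,
    sigma_resid = 7.0,
    gamma0 = 0.20,
    gamma1 = 1.44,
    sigma_avulsion_re = 0.7,
    delta0 = -1.0,
    delta1 = -0.45,
    metal_temp_range = c(-40, 2),
    p_poor_quality_apex = 0.60
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown generator parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    params[names(overrides)] <- overrides
  }
  stopifnot(params$kappa > 0, params$sigma_batch >= 0,
            params$sigma_tongue >= 0, params$sigma_resid >= 0,
            params$sigma_avulsion_re >= 0)
  structure(params, class = "tt_generator_params")
}

#' @export
print.tt_generator_params <- function(x, ...) {
  cat("Generator parameters for the synthetic detachment experiment\n")
  cat(sprintf("  force cell means (N): %s\n",
              paste(sprintf("%s=%.1f", names(x$cell_mean_force),
                            x$cell_mean_force), collapse = ", ")))
  cat(sprintf("  beta_contact = %.2f N/s; quadratic temp effect: kappa = %.4f N/degC^2, peak at %.1f degC\n",
              x$beta_contact, x$kappa, x$T_peak))
  cat(sprintf("  force SDs (N): batch %.1f, tongue %.1f, residual %.1f\n",
              x$sigma_batch, x$sigma_tongue, x$sigma_resid))
  cat(sprintf("  avulsion: logit = %.2f + %.2f z(force) + N(0, %.2f^2)\n",
              x$gamma0, x$gamma1, x$sigma_avulsion_re))
  cat(sprintf("  cold injury: logit = %.2f + %.2f * metal_temp\n",
              x$delta0, x$delta1))
  invisible(x)
}

## Row of the covariate table for given region/release vectors.
cell_index <- function(params, region, release) {
  idx <- match(paste(region, release),
               paste(params$covariates$region, params$covariates$release))
  if (anyNA(idx)) {
    stop("unknown region/release cell label", call. = FALSE)
  }
  idx
}

## Expected metal temperature per record under the truncated sampling
## distribution of its cell (used to centre the quadratic temperature
## effect so cell mean forces are preserved).
cell_metal_temp_mean <- function(params, region, release) {
  cov <- params$covariates
  mu <- vapply(seq_len(nrow(cov)), function(i) {
    trunc_norm_mean(cov$metal_temp_mean[i], cov$metal_temp_sd[i],
                    params$metal_temp_range[1], params$metal_temp_range[2])
  }, numeric(1))
  mu[cell_index(params, region, release)]
}

## Expected contact time per record (gamma means are exact).
cell_contact_mean <- function(params, region, release) {
  cov <- params$covariates
  (cov$application_mean + cov$detachment_mean)[
    cell_index(params, region, release)]
}
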