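#' Fit the random-intercept logistic model for avulsion injury
#'
#' Two model forms are supported, mirroring the study's analysis: the
#' force-only model (avulsion on peak detachment force, z-scored within
#' the analysis dataset, so the slope is per SD of force) and the
#' four-variable model (contact time, tongue region, release type, metal
#' temperature).  Both include a per-tongue random intercept, fitted by
#' adaptive Gauss-Hermite quadrature (15 nodes), falling back to the
#' Laplace approximation if the quadrature fit does not converge.
#'
#' @param records data frame of trials with an `avulsion` column.
#' @param predictors `"force"` (default) or `"four_var"`.
#' @param nagq number of quadrature nodes (default 15).
#' @return Object of class `tt_risk_fit`: `coefficients` (named log-odds
#'   terms), `var_random_intercept`, `log_likelihood`, `model_kind`,
#'   `force_center`/`force_scale` (force-only model: the mean/SD used for
#'   z-scoring), `converged`, `separation` flag, and the `lme4` `model`.
#' @examples
#' \donttest{
#' d <- simulate_study(seed = 1)
#' fit <- fit_avulsion_model(d)
#' fit$coefficients["force_z"]                    # about 1.44
#' 100 * (exp(fit$coefficients["force_z"]) - 1)   # percent odds change
#' }
#' @export
fit_avulsion_model <- function(records, predictors = c("force", "four_var"),
                               nagq = 15L) {
  predictors <- match.arg(predictors)
  stop_if_not_records(records, c("avulsion", "tongue_id", "batch_id"))
  if (length(unique(records$avulsion)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  d <- records
  d$tongue <- factor(paste(d$batch_id, d$tongue_id, sep = ":"))
  if (predictors == "force") {
    stop_if_not_records(records, "peak_force")
    center <- mean(d$peak_force)
    scale <- stats::sd(d$peak_force)
    d$force_z <- (d$peak_force - center) / scale
    form <- avulsion ~ force_z + (1 | tongue)
    kind <- "avulsion_force"
  } else {
    stop_if_not_records(records, c("contact_time", "region", "release",
                                   "metal_temp"))
    d$region <- factor(d$region, levels = c("apex", "basis"))
    d$release <- factor(d$release, levels = c("gradual", "rapid"))
    form <- avulsion ~ contact_time + region + release + metal_temp +
      (1 | tongue)
    kind <- "avulsion_4var"
    center <- NA_real_
    scale <- NA_real_
  }
  fit <- fit_glmm_quadrature(form, d, nagq)
  res <- risk_fit_from_glmer(fit, kind)
  res$force_center <- center
  res$force_scale <- scale
  res
}

#' Fit the random-intercept logistic model for cold injury
#'
#' Covariates are metal temperature, contact time and tongue region;
#' release type is excluded (detachment mode cannot plausibly affect
#' freezing).  A colder metal surface is expected to raise the risk, so
#' the temperature coefficient should be negative.  When the outcome is
#' nearly degenerate (over 98\% positive, as in the real experiment) the
#' model is still fitted but a warning notes that the fit is fragile.
#'
#' @param records data frame of trials with a `cold_injury` column.
#' @param nagq number of quadrature nodes (default 15).
#' @return Object of class `tt_risk_fit` with `model_kind = "cold_3var"`.
#' @export
fit_cold_model <- function(records, nagq = 15L) {
  stop_if_not_records(records, c("cold_injury", "metal_temp",
                                 "contact_time", "region", "tongue_id",
                                 "batch_id"))
  if (length(unique(records$cold_injury)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  rate <- mean(records$cold_injury)
  if (rate > 0.98 || rate < 0.02) {
    warning(sprintf(
      "cold-injury outcome nearly degenerate (%.0f%% positive); risk model is fragile",
      100 * rate), call. = FALSE)
  }
  d <- records
  d$tongue <- factor(paste(d$batch_id, d$tongue_id, sep = ":"))
  d$region <- factor(d$region, levels = c("apex", "basis"))
  fit <- fit_glmm_quadrature(
    cold_injury ~ metal_temp + contact_time + region + (1 | tongue), d, nagq)
  risk_fit_from_glmer(fit, "cold_3var")
}

## glmer with adaptive Gauss-Hermite quadrature, Laplace fallback.
fit_glmm_quadrature <- function(form, data, nagq) {
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = data, family = stats::binomial("logit"),
                nAGQ = nagq,
                control = lme4::glmerControl(tolPwrss = 1e-9))))
  if (!is.null(fit@optinfo$conv$lme4$messages) && nagq != 1L) {
    refit <- suppressMessages(suppressWarnings(
      lme4::glmer(form, data = data, family = stats::binomial("logit"),
                  nAGQ = 1L)))
    if (is.null(refit@optinfo$conv$lme4$messages)) fit <- refit
  }
  fit
}

risk_fit_from_glmer <- function(fit, kind) {
  beta <- lme4::fixef(fit)
  names(beta) <- sub("^\\(Intercept\\)$", "intercept", names(beta))
  names(beta) <- sub("^regionbasis$", "region_basis", names(beta))
  names(beta) <- sub("^releaserapid$", "release_rapid", names(beta))
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ## crude separation flag: enormous slope or SE on the logit scale
  separation <- any(abs(beta) > 15) || any(se > 15)
  structure(list(
    coefficients = beta,
    se = stats::setNames(se, names(beta)),
    var_random_intercept = vc$vcov[1],
    log_likelihood = as.numeric(stats::logLik(fit)),
    model_kind = kind,
    converged = is.null(fit@optinfo$conv$lme4$messages),
    separation = separation,
    model = fit
  ), class = "tt_risk_fit")
}

#' @export
print.tt_risk_fit <- function(x, ...) {
  cat(sprintf("Random-intercept logistic model (%s)\n", x$model_kind))
  print(round(x$coefficients, 4))
  cat(sprintf("random-intercept variance %.3f, logLik %.2f%s%s\n",
              x$var_random_intercept, x$log_likelihood,
              if (x$converged) "" else "  [convergence flagged]",
              if (x$separation) "  [possible separation]" else ""))
  invisible(x)
}

#' Default grid of experimental conditions
#'
#' Cartesian product of metal temperatures -40 to 0 degC in 5 degC steps,
#' contact times 3/5/7/9 s, both regions and both release types.
#'
#' @return Data frame with columns `metal_temp`, `contact_time`,
#'   `region`, `release`.
#' @export
default_grid_axes <- function() {
  expand.grid(metal_temp = seq(-40, 0, by = 5),
              contact_time = c(3, 5, 7, 9),
              region = c("apex", "basis"),
              release = c("gradual", "rapid"),
              stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Predict detachment force over a grid of conditions
#'
#' Fixed-effects-only prediction (random effects at zero) from a force
#' model fit at every node of a condition grid — the first stage of the
#' two-stage risk-surface procedure.
#'
#' @param force_fit a [fit_force_lmm()] result (quadratic recommended).
#' @param grid data frame of conditions (see [default_grid_axes()]).
#' @return `grid` with a `predicted_force` column (N).  Temperatures
#'   outside [-40, +2] degC trigger an extrapolation warning.
#' @export
predict_force_grid <- function(force_fit, grid = default_grid_axes()) {
  stopifnot(inherits(force_fit, "tt_force_fit"))
  stop_if_not_records(grid, c("metal_temp", "contact_time", "region",
                              "release"))
  if (any(grid$metal_temp < -40 | grid$metal_temp > 2)) {
    warning("grid extrapolates beyond the calibrated [-40, +2] degC range",
            call. = FALSE)
  }
  fe <- force_fit$fixed_effects
  pred <- fe[["intercept"]] +
    fe[["contact_time"]] * grid$contact_time +
    fe[["region_basis"]] * (grid$region == "basis") +
    fe[["release_rapid"]] * (grid$release == "rapid") +
    fe[["temp"]] * grid$metal_temp
  if (!is.na(fe["temp_sq"])) {
    pred <- pred + fe[["temp_sq"]] * grid$metal_temp^2
  }
  grid$predicted_force <- unname(pred)
  grid
}

#' Avulsion risk over a grid of predicted forces
#'
#' Second stage of the risk-surface procedure: the force-only avulsion
#' model is evaluated at each node's predicted force,
#' `risk = plogis(intercept + slope * z(force))`, z-scoring with the
#' model's training mean/SD and the random intercept at zero
#' (population-level risk).
#'
#' @param risk_fit a force-only [fit_avulsion_model()] result.
#' @param grid_with_forces grid with a `predicted_force` column from
#'   [predict_force_grid()].
#' @return The grid with a `risk` column in [0, 1].
#' @export
risk_surface <- function(risk_fit, grid_with_forces) {
  stopifnot(inherits(risk_fit, "tt_risk_fit"))
  if (risk_fit$model_kind != "avulsion_force") {
    stop("`risk_fit` must be the force-only avulsion model", call. = FALSE)
  }
  stop_if_not_records(grid_with_forces, "predicted_force")
  z <- (grid_with_forces$predicted_force - risk_fit$force_center) /
    risk_fit$force_scale
  grid_with_forces$risk <- stats::plogis(
    risk_fit$coefficients[["intercept"]] +
      risk_fit$coefficients[["force_z"]] * z)
  grid_with_forces
}
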