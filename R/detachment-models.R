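#' Fit the linear mixed model for peak detachment force
#'
#' Fits, by maximum likelihood, the force analysis model: fixed effects
#' for contact time, tongue region (basis vs apex), release type (rapid
#' vs gradual) and metal temperature (linear, optionally plus a quadratic
#' term), with random intercepts for slaughter batch and for tongue
#' nested within batch.  ML (not REML) is used throughout so that
#' likelihood-ratio tests and AIC comparisons between nested fits are
#' valid.  Metal temperature is centred at its sample mean before
#' squaring to reduce collinearity; reported coefficients are
#' back-transformed to natural units (N per s, per degC, per degC^2).
#'
#' @param records data frame of trials with `peak_force`, `contact_time`,
#'   `region`, `release`, `metal_temp`, `tongue_id`, `batch_id`.
#' @param include_quadratic add the squared metal-temperature term?
#' @return An object of class `tt_force_fit`: list with `fixed_effects`
#'   (named vector on natural units: intercept, contact_time,
#'   region_basis, release_rapid, temp, and temp_sq if requested),
#'   `var_batch`, `var_tongue`, `var_resid` (N^2), `log_likelihood`,
#'   `n_params`, `aic`, `converged`, `temp_center` (degC), and the
#'   underlying `lme4` fit as `model`.
#' @examples
#' \donttest{
#' d <- simulate_study(seed = 1)
#' fit <- fit_force_lmm(d, include_quadratic = TRUE)
#' fit$fixed_effects
#' peak_temperature(fit)
#' }
#' @export
fit_force_lmm <- function(records, include_quadratic = FALSE) {
  stop_if_not_records(records, c("peak_force", "contact_time", "region",
                                 "release", "metal_temp", "tongue_id",
                                 "batch_id"))
  if (nrow(records) < 30L) {
    stop("need at least 30 records to fit the force model", call. = FALSE)
  }
  if (length(unique(records$region)) < 2L ||
      length(unique(records$release)) < 2L) {
    stop("both regions and both release types must be present",
         call. = FALSE)
  }
  d <- records
  d$region <- factor(d$region, levels = c("apex", "basis"))
  d$release <- factor(d$release, levels = c("gradual", "rapid"))
  d$batch <- factor(d$batch_id)
  d$tongue <- factor(paste(d$batch_id, d$tongue_id, sep = ":"))
  temp_center <- mean(d$metal_temp)
  d$temp_c <- d$metal_temp - temp_center
  form <- if (include_quadratic) {
    peak_force ~ contact_time + region + release + temp_c + I(temp_c^2) +
      (1 | batch) + (1 | tongue)
  } else {
    peak_force ~ contact_time + region + release + temp_c +
      (1 | batch) + (1 | tongue)
  }
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = FALSE))
  conv <- is.null(fit@optinfo$conv$lme4$messages) &&
    fit@optinfo$conv$opt == 0
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_of <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  ## back-transform centred-temperature coefficients to natural degC units
  fe <- c(intercept = unname(beta[["(Intercept)"]]),
          contact_time = unname(beta[["contact_time"]]),
          region_basis = unname(beta[["regionbasis"]]),
          release_rapid = unname(beta[["releaserapid"]]),
          temp = unname(beta[["temp_c"]]))
  if (include_quadratic) {
    b2 <- unname(beta[["I(temp_c^2)"]])
    fe[["temp"]] <- fe[["temp"]] - 2 * b2 * temp_center
    fe[["temp_sq"]] <- b2
    fe[["intercept"]] <- fe[["intercept"]] - beta[["temp_c"]] * temp_center +
      b2 * temp_center^2
  } else {
    fe[["intercept"]] <- fe[["intercept"]] - fe[["temp"]] * temp_center
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  structure(list(
    fixed_effects = fe,
    var_batch = var_of("batch"),
    var_tongue = var_of("tongue"),
    var_resid = var_of("Residual"),
    log_likelihood = ll,
    n_params = k,
    aic = -2 * ll + 2 * k,
    converged = conv,
    temp_center = temp_center,
    quadratic = include_quadratic,
    n = nrow(d),
    model = fit
  ), class = "tt_force_fit")
}

#' @export
print.tt_force_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model for peak detachment force (%s, ML, n = %d)\n",
              if (x$quadratic) "quadratic in metal temperature" else "linear",
              x$n))
  print(round(x$fixed_effects, 4))
  cat(sprintf("random-effect variances (N^2): batch %.2f, tongue %.2f, residual %.2f\n",
              x$var_batch, x$var_tongue, x$var_resid))
  cat(sprintf("logLik %.2f, %d parameters, AIC %.1f%s\n", x$log_likelihood,
              x$n_params, x$aic,
              if (x$converged) "" else "  [convergence flagged]"))
  invisible(x)
}

#' Metal temperature of maximal adhesion from a quadratic fit
#'
#' Vertex of the fitted parabola in natural temperature units,
#' \eqn{-\beta_T / (2 \beta_{T^2})}.  Requires a concave quadratic
#' temperature effect (negative squared-term coefficient).
#'
#' @param fit a quadratic [fit_force_lmm()] result.
#' @return Peak-adhesion metal temperature in degC.
#' @examples
#' \donttest{
#' fit <- fit_force_lmm(simulate_study(seed = 1), include_quadratic = TRUE)
#' peak_temperature(fit)   # near -7.5
#' }
#' @export
peak_temperature <- function(fit) {
  stopifnot(inherits(fit, "tt_force_fit"))
  b2 <- fit$fixed_effects["temp_sq"]
  if (is.na(b2)) stop("fit has no quadratic temperature term", call. = FALSE)
  if (b2 >= 0) {
    stop("no interior maximum: quadratic temperature coefficient is not negative",
         call. = FALSE)
  }
  unname(-fit$fixed_effects["temp"] / (2 * b2))
}

#' Compare nested force models by likelihood ratio and AIC
#'
#' @param fit_linear,fit_quadratic nested ML fits on identical records
#'   (linear = reduced, quadratic = extended).  The LR statistic is
#'   `2 * (ll_extended - ll_reduced)`, clamped at zero with a warning if
#'   optimiser noise makes it negative; `delta_aic` is
#'   `aic_reduced - aic_extended` (positive favours the extended model);
#'   the Akaike weight of the preferred model is
#'   `1 / (1 + exp(-|delta_aic| / 2))`.
#' @return Object of class `tt_model_comparison` with `chi_sq`, `df`,
#'   `p_value`, `delta_aic`, `akaike_weight_preferred`.
#' @seealso [comparison_from_chisq()] for the closed-form arithmetic from
#'   a printed chi-square statistic.
#' @export
compare_models <- function(fit_linear, fit_quadratic) {
  stopifnot(inherits(fit_linear, "tt_force_fit"),
            inherits(fit_quadratic, "tt_force_fit"))
  if (fit_linear$n != fit_quadratic$n) {
    stop("fits must be on identical records", call. = FALSE)
  }
  df <- fit_quadratic$n_params - fit_linear$n_params
  chi_sq <- 2 * (fit_quadratic$log_likelihood - fit_linear$log_likelihood)
  if (chi_sq < 0) {
    warning("extended model has lower likelihood; LR statistic clamped at 0",
            call. = FALSE)
    chi_sq <- 0
  }
  delta_aic <- fit_linear$aic - fit_quadratic$aic
  p <- if (df > 0) stats::pchisq(chi_sq, df, lower.tail = FALSE) else NA_real_
  structure(list(
    chi_sq = chi_sq, df = df, p_value = p, delta_aic = delta_aic,
    akaike_weight_preferred = 1 / (1 + exp(-abs(delta_aic) / 2))
  ), class = "tt_model_comparison")
}

#' Model-comparison arithmetic from a printed likelihood-ratio statistic
#'
#' For two nested ML fits differing by `df` parameters,
#' `delta_aic = chi_sq - 2 * df` and the Akaike weight of the extended
#' model is `1 / (1 + exp(-delta_aic / 2))`.  Useful for recomputing a
#' reported AIC difference and weight from a reported chi-square.
#'
#' @param chi_sq likelihood-ratio statistic.
#' @param df parameter difference between the nested fits.
#' @return Object of class `tt_model_comparison`.
#' @examples
#' cmp <- comparison_from_chisq(9.99, 1)
#' cmp$delta_aic                 # 7.99
#' cmp$akaike_weight_preferred   # 0.982
#' @export
comparison_from_chisq <- function(chi_sq, df = 1L) {
  stopifnot(chi_sq >= 0, df >= 1)
  delta_aic <- chi_sq - 2 * df
  structure(list(
    chi_sq = chi_sq, df = df,
    p_value = stats::pchisq(chi_sq, df, lower.tail = FALSE),
    delta_aic = delta_aic,
    akaike_weight_preferred = 1 / (1 + exp(-delta_aic / 2))
  ), class = "tt_model_comparison")
}

#' @export
print.tt_model_comparison <- function(x, ...) {
  cat(sprintf("Nested model comparison: chi^2(%d) = %.2f, p = %.3g\n",
              x$df, x$chi_sq, x$p_value))
  cat(sprintf("delta AIC = %.2f, Akaike weight of preferred model = %.3f\n",
              x$delta_aic, x$akaike_weight_preferred))
  invisible(x)
}

#' Sample size for testing a single regression coefficient
#'
#' Smallest total N giving at least the target power for a two-tailed
#' test of one coefficient in a fixed linear model, using the noncentral
#' t distribution with noncentrality `sqrt(f2 * N)` and
#' `N - n_predictors - 1` degrees of freedom (the "fixed model, single
#' regression coefficient" power calculation).  Also reports the N
#' inflated for anticipated attrition, both as `ceiling(N / (1 -
#' attrition))` and `ceiling(N * (1 + attrition))` (the inflation
#' convention differs between tools, so both candidates are given).
#'
#' @param f2 Cohen effect size f^2 (default 0.1, small-to-moderate).
#' @param alpha two-tailed significance level (default 0.0125, a
#'   Bonferroni-corrected 0.05/4).
#' @param power target power (default 0.90).
#' @param n_predictors number of predictors in the model (default 4).
#' @param attrition anticipated proportion of failed experiments
#'   (default 0.15).
#' @return List with `n_required`, `power_achieved`,
#'   `n_inflated_divide` (`ceiling(n / (1 - attrition))`) and
#'   `n_inflated_multiply` (`ceiling(n * (1 + attrition))`).
#' @examples
#' required_sample_size(f2 = 0.1, alpha = 0.05, power = 0.80,
#'                      n_predictors = 1)$n_required   # 79
#' @export
required_sample_size <- function(f2 = 0.1, alpha = 0.0125, power = 0.90,
                                 n_predictors = 4L, attrition = 0.15) {
  stopifnot(f2 > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            n_predictors >= 1, attrition >= 0, attrition < 1)
  pow <- function(n) {
    df <- n - n_predictors - 1
    if (df < 1) return(0)
    tcrit <- stats::qt(1 - alpha / 2, df)
    ncp <- sqrt(f2 * n)
    stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp,
                                           lower.tail = FALSE)
  }
  n <- n_predictors + 2L
  while (pow(n) < power) {
    n <- n + 1L
    if (n > 1e6) stop("target power unreachable", call. = FALSE)
  }
  list(n_required = n,
       power_achieved = pow(n),
       n_inflated_divide = as.integer(ceiling(n / (1 - attrition))),
       n_inflated_multiply = as.integer(ceiling(n * (1 + attrition))))
}

#' Per-condition summary table
#'
#' Mean (SD) of every numeric trial variable and count (proportion) of
#' every logical one, within each tongue region x release cell — the
#' layout of the experiment's conditions-and-outcomes table.
#'
#' @param records data frame of trials.
#' @return Long data frame with columns `region`, `release`, `n_cell`,
#'   `variable`, `mean`, `sd`, `count`, `prop`.  Numeric variables fill
#'   `mean`/`sd` (NaN/NA for empty cells); logical variables fill
#'   `count`/`prop`.
#' @export
summarize_by_condition <- function(records) {
  stop_if_not_records(records, c("region", "release"))
  vars <- setdiff(names(records),
                  c("tongue_id", "batch_id", "region", "release"))
  cells <- expand.grid(region = c("apex", "basis"),
                       release = c("gradual", "rapid"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$region == cells$region[i] &
      records$release == cells$release[i]
    sub <- records[sel, , drop = FALSE]
    do.call(rbind, lapply(vars, function(v) {
      x <- sub[[v]]
      row <- data.frame(region = cells$region[i], release = cells$release[i],
                        n_cell = nrow(sub), variable = v,
                        mean = NA_real_, sd = NA_real_,
                        count = NA_integer_, prop = NA_real_,
                        stringsAsFactors = FALSE)
      if (is.logical(x)) {
        row$count <- sum(x)
        row$prop <- if (nrow(sub)) mean(x) else NaN
      } else if (is.numeric(x)) {
        row$mean <- if (nrow(sub)) mean(x) else NaN
        row$sd <- if (nrow(sub) > 1) stats::sd(x) else NA_real_
      } else {
        return(NULL)
      }
      row
    }))
  }))
  rownames(out) <- NULL
  out
}
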