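test_that("force-only avulsion model recovers the generator slope", {
  slopes <- vapply(1:3, function(s) {
    fit_avulsion_model(study_2000(s))$coefficients[["force_z"]]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1.44), 0.2)
  ## per-SD slope translates to the reported percent odds increase
  expect_equal(100 * (exp(1.44) - 1), 322.07, tolerance = 1e-3)
})

test_that("a null force effect is recovered as null", {
  d <- study_2000(9, params = generator_params(gamma1 = 0))
  fit <- fit_avulsion_model(d)
  slope <- fit$coefficients[["force_z"]]
  se <- fit$se[["force_z"]]
  expect_lt(abs(slope), 0.2)
  expect_true(slope - 1.96 * se < 0 && slope + 1.96 * se > 0)
})

test_that("slope recovery is unbiased across generator slopes", {
  ## stochastic battery at n = 5000; bias is a mean, so average seeds
  for (g1 in c(0.5, 1.44)) {
    got <- vapply(1:3, function(s) {
      d <- simulate_study(n_tongues = 2500L, batch_size = 4L,
                          n_excluded = 0L,
                          params = generator_params(gamma1 = g1),
                          seed = 300 + round(100 * g1) + s)
      fit_avulsion_model(d)$coefficients[["force_z"]]
    }, numeric(1))
    expect_lt(abs(mean(got) - g1) / g1, 0.10)
  }
})

test_that("four-variable avulsion model fits and reports all terms", {
  fit <- fit_avulsion_model(default_study(), predictors = "four_var")
  expect_setequal(names(fit$coefficients),
                  c("intercept", "contact_time", "region_basis",
                    "release_rapid", "metal_temp"))
  expect_equal(fit$model_kind, "avulsion_4var")
  expect_gte(fit$var_random_intercept, 0)
})

test_that("cold-injury model finds colder metal riskier", {
  fit <- fit_cold_model(default_study())
  expect_lt(fit$coefficients[["metal_temp"]], 0)
  ## plug-in risk at +1 degC is below the risk at -10 degC
  eta <- function(Tm) {
    fit$coefficients[["intercept"]] + fit$coefficients[["metal_temp"]] * Tm +
      fit$coefficients[["contact_time"]] * 7
  }
  expect_lt(plogis(eta(1)), plogis(eta(-10)))
})

test_that("a null temperature effect on cold injury is recovered as null", {
  d <- study_2000(13, params = generator_params(delta1 = 0, delta0 = 1.5))
  fit <- fit_cold_model(d)
  expect_lt(abs(fit$coefficients[["metal_temp"]]), 0.03)
})

test_that("nearly degenerate cold-injury outcomes warn but still fit", {
  d <- study_2000(14, params = generator_params(delta0 = 2))
  expect_gt(mean(d$cold_injury), 0.98)
  expect_warning(fit_cold_model(d), "degenerate")
})

test_that("force grid prediction is linear, peaked, and ordered", {
  fit <- fit_force_lmm(study_2000(4), include_quadratic = TRUE)
  grid <- predict_force_grid(fit)
  expect_equal(nrow(grid), 9 * 4 * 2 * 2)
  ## contact time +1 s raises force by exactly the contact coefficient
  g1 <- grid[grid$contact_time == 3, ]
  g2 <- grid[grid$contact_time == 5, ]
  expect_equal(g2$predicted_force - g1$predicted_force,
               rep(2 * fit$fixed_effects[["contact_time"]], nrow(g1)))
  ## rapid release never below gradual at matching nodes
  gr <- grid[grid$release == "gradual", ]
  ra <- grid[grid$release == "rapid", ]
  expect_true(all(ra$predicted_force >= gr$predicted_force))
  ## within a column the force peaks at the node nearest the fitted vertex
  col <- grid[grid$contact_time == 7 & grid$region == "basis" &
                grid$release == "rapid", ]
  Tstar <- col$metal_temp[which.max(col$predicted_force)]
  vertex <- peak_temperature(fit)
  expect_equal(Tstar, col$metal_temp[which.min(abs(col$metal_temp - vertex))])
  expect_lt(abs(vertex - (-7.5)), 3)
  expect_warning(
    predict_force_grid(fit, data.frame(metal_temp = -55, contact_time = 5,
                                       region = "apex",
                                       release = "gradual")),
    "extrapolates")
})

test_that("risk surface is a monotone map of predicted force", {
  ## a large study keeps the fitted vertex well-determined, so the
  ## risk maximum sits where the adhesion peak is
  d <- study_2000(4)
  force_fit <- fit_force_lmm(d, include_quadratic = TRUE)
  risk_fit <- fit_avulsion_model(d)
  surf <- risk_surface(risk_fit, predict_force_grid(force_fit))
  expect_true(all(surf$risk >= 0 & surf$risk <= 1))
  ord <- order(surf$predicted_force)
  expect_true(all(diff(surf$risk[ord]) >= -1e-12))
  ## highest risk sits in the moderately-cold temperature band
  best <- surf[which.max(surf$risk), ]
  expect_gte(best$metal_temp, -15)
  expect_lte(best$metal_temp, -5)
  ## a zero slope flattens the surface at the intercept risk
  flat_fit <- risk_fit
  flat_fit$coefficients["force_z"] <- 0
  flat <- risk_surface(flat_fit, predict_force_grid(force_fit))
  expect_equal(unique(round(flat$risk, 12)),
               round(plogis(risk_fit$coefficients[["intercept"]]), 12))
})

test_that("risk probabilities are invariant to the force unit", {
  d <- default_study()
  force_fit <- fit_force_lmm(d, include_quadratic = TRUE)
  grid <- predict_force_grid(force_fit)
  fit_n <- fit_avulsion_model(d)
  d_kn <- d
  d_kn$peak_force <- d$peak_force * 1000
  fit_kn <- fit_avulsion_model(d_kn)
  grid_kn <- grid
  grid_kn$predicted_force <- grid$predicted_force * 1000
  r1 <- risk_surface(fit_n, grid)$risk
  r2 <- risk_surface(fit_kn, grid_kn)$risk
  expect_equal(r1, r2, tolerance = 1e-4)
})

test_that("in-sample plug-in risk calibrates to the observed injury rate", {
  d <- default_study()
  fit <- fit_avulsion_model(d)
  z <- (d$peak_force - fit$force_center) / fit$force_scale
  plug_in <- plogis(fit$coefficients[["intercept"]] +
                      fit$coefficients[["force_z"]] * z)
  expect_lt(abs(mean(plug_in) - mean(d$avulsion)), 0.02)
})

test_that("risk-model preconditions are enforced", {
  d <- default_study()
  d$avulsion <- TRUE
  expect_error(fit_avulsion_model(d), "both outcome classes")
  fit4 <- fit_avulsion_model(default_study(), predictors = "four_var")
  expect_error(risk_surface(fit4, data.frame(predicted_force = 1)),
               "force-only")
})
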