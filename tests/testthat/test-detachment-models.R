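test_that("noise-free data are fit exactly and match a least-squares oracle", {
  ## additive truth with common covariate distributions, so the
  ## main-effects analysis model is correctly specified and the
  ## deterministic fit must be exact
  p <- noise_free_params()
  p$cell_mean_force <- c(apex.gradual = 10, apex.rapid = 15,
                         basis.gradual = 14, basis.rapid = 19)
  p$covariates$application_mean <- 4.0
  p$covariates$application_sd <- 1.8
  p$covariates$detachment_mean <- 3.0
  p$covariates$detachment_sd <- 1.6
  p$covariates$metal_temp_mean <- -13.5
  p$covariates$metal_temp_sd <- 8.0
  d <- simulate_study(n_tongues = 200L, batch_size = 4L, n_excluded = 0L,
                      params = p, seed = 2)
  ## a zero-variance response makes the mixed fit singular by design
  fit <- suppressWarnings(fit_force_lmm(d, include_quadratic = TRUE))
  expect_equal(unname(fit$fixed_effects["contact_time"]), 1.0,
               tolerance = 1e-6)
  expect_equal(unname(fit$fixed_effects["temp_sq"]), -p$kappa,
               tolerance = 1e-6)
  ## natural-unit linear term of -kappa (T - T_peak)^2 is 2 kappa T_peak
  expect_equal(unname(fit$fixed_effects["temp"]), 2 * p$kappa * p$T_peak,
               tolerance = 1e-6)
  ## closed-form least-squares oracle on the same design matrix
  X <- cbind(1, d$contact_time, d$region == "basis", d$release == "rapid",
             d$metal_temp, d$metal_temp^2)
  beta <- qr.solve(X, d$peak_force)
  expect_equal(unname(fit$fixed_effects), unname(beta), tolerance = 1e-6)
})

test_that("default-study fits show the expected effect directions", {
  d <- default_study()
  fit <- fit_force_lmm(d, include_quadratic = TRUE)
  expect_gt(fit$fixed_effects[["release_rapid"]], 0)
  expect_gt(fit$fixed_effects[["region_basis"]], 0)
  expect_true(is.finite(fit$log_likelihood))
})

test_that("the quadratic temperature term is concave on large samples", {
  fit <- fit_force_lmm(study_2000(5), include_quadratic = TRUE)
  expect_lt(fit$fixed_effects[["temp_sq"]], 0)
})

test_that("quadratic refits recover generator truth within 15%", {
  ## fixed-seed battery, n = 5000 per seed
  fits <- lapply(1:3, function(s) {
    d <- simulate_study(n_tongues = 2500L, batch_size = 4L,
                        n_excluded = 0L, seed = 100 + s)
    fit_force_lmm(d, include_quadratic = TRUE)
  })
  avg <- function(f) mean(vapply(fits, f, numeric(1)))
  expect_lt(abs(avg(function(f) f$fixed_effects[["contact_time"]]) - 1.0),
            0.15)
  expect_lt(abs(avg(function(f) f$fixed_effects[["temp_sq"]]) - (-0.008)),
            0.15 * 0.008)
  expect_lt(abs(avg(function(f) f$var_resid) - 49), 0.15 * 49)
  between <- avg(function(f) f$var_batch + f$var_tongue)
  expect_lt(abs(between - (1.5^2 + 3^2)), 0.35 * (1.5^2 + 3^2))
})

test_that("AIC identity holds for every fit", {
  d <- default_study()
  for (q in c(FALSE, TRUE)) {
    fit <- fit_force_lmm(d, include_quadratic = q)
    expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$n_params)
    expect_gte(fit$var_batch, 0)
    expect_gte(fit$var_tongue, 0)
    expect_gte(fit$var_resid, 0)
  }
})

test_that("peak_temperature is the parabola vertex in natural units", {
  fake <- structure(list(fixed_effects = c(temp = -0.12, temp_sq = -0.008)),
                    class = "tt_force_fit")
  expect_equal(peak_temperature(fake), -7.5)
  fake$fixed_effects["temp"] <- 0
  expect_equal(peak_temperature(fake), 0)
  fake$fixed_effects["temp_sq"] <- 0.008
  expect_error(peak_temperature(fake), "no interior maximum")
  expect_error(peak_temperature(structure(
    list(fixed_effects = c(temp = 1)), class = "tt_force_fit")),
    "no quadratic")
})

test_that("model comparison arithmetic and antisymmetry hold", {
  d <- default_study()
  f0 <- fit_force_lmm(d, FALSE)
  f1 <- fit_force_lmm(d, TRUE)
  cmp <- compare_models(f0, f1)
  expect_equal(cmp$chi_sq, 2 * (f1$log_likelihood - f0$log_likelihood))
  expect_equal(cmp$delta_aic, f0$aic - f1$aic)
  swapped <- suppressWarnings(compare_models(f1, f0))
  expect_equal(swapped$delta_aic, -cmp$delta_aic)
  ## identical fits: no evidence either way
  same <- compare_models(f0, f0)
  expect_equal(same$chi_sq, 0)
  expect_equal(same$akaike_weight_preferred, 0.5)
})

test_that("printed chi-square reproduces the reported AIC difference and weight", {
  cmp <- comparison_from_chisq(9.99, 1)
  expect_equal(cmp$delta_aic, 7.99)
  expect_equal(cmp$akaike_weight_preferred, 1 / (1 + exp(-7.99 / 2)))
  expect_equal(round(cmp$akaike_weight_preferred, 2), 0.98)
  expect_lt(cmp$p_value, 0.01)
})

test_that("required sample size matches the noncentral-F oracle", {
  ## oracle: brute-force power from the noncentral F distribution
  pow_F <- function(N, f2, a, p) {
    df2 <- N - p - 1
    1 - pf(qf(1 - a, 1, df2), 1, df2, ncp = f2 * N)
  }
  res <- required_sample_size(0.1, 0.05, 0.80, 1)
  expect_lt(pow_F(res$n_required - 1, 0.1, 0.05, 1), 0.80)
  expect_gte(pow_F(res$n_required, 0.1, 0.05, 1), 0.80)
  expect_equal(res$n_required, 81L)
  ## the study's own specification lands near its 85-tongue / 170-trial plan
  spec <- required_sample_size()
  expect_gte(spec$n_required, 140)
  expect_lte(spec$n_required, 150)
  expect_true(any(abs(c(spec$n_inflated_divide,
                        spec$n_inflated_multiply) - 170) <= 3))
  ## enormous effects need only the minimum identifiable N
  expect_equal(required_sample_size(1e6, 0.05, 0.8, 4)$n_required, 4L + 2L)
  expect_error(required_sample_size(-1), "f2")
})

test_that("per-condition summary partitions the dataset", {
  d <- default_study()
  tab <- summarize_by_condition(d)
  counts <- unique(tab[, c("region", "release", "n_cell")])
  expect_equal(sum(counts$n_cell), nrow(d))
  expect_setequal(unique(tab$variable),
                  setdiff(names(d), c("tongue_id", "batch_id", "region",
                                      "release")))
  ## logical variables report counts, numeric report means
  av <- tab[tab$variable == "avulsion", ]
  expect_true(all(!is.na(av$count)))
  ## empty cell yields NaN means and zero counts
  sub <- d[!(d$region == "apex" & d$release == "rapid"), ]
  tab2 <- summarize_by_condition(sub)
  empty <- tab2[tab2$region == "apex" & tab2$release == "rapid", ]
  expect_true(all(empty$n_cell == 0L))
  expect_true(all(is.nan(empty$mean[empty$variable == "peak_force"])))
})

test_that("apex-gradual mean force matches the calibration target", {
  x <- cell_records("apex", "gradual", 20000, seed = 51)
  expect_lt(abs(mean(x$peak_force) - 10.9), 0.6)
})

test_that("force model preconditions are enforced", {
  d <- default_study()
  expect_error(fit_force_lmm(d[1:10, ]), "30 records")
  expect_error(fit_force_lmm(d[d$region == "apex", ]), "both regions")
})
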