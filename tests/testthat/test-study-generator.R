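test_that("block-randomized design has the study's size and balance", {
  d <- build_design(84, 6, seed = 1)
  expect_equal(nrow(d), 168L)
  expect_equal(length(unique(d$batch_id)), 14L)
  ## every tongue appears exactly twice, once per region
  per_tongue <- table(d$tongue_id)
  expect_true(all(per_tongue == 2L))
  expect_equal(unname(colSums(table(d$region, d$tongue_id) == 1L)),
               rep(2L, 84L))
  ## within each batch and region, releases are balanced
  for (b in unique(d$batch_id)) {
    for (r in c("apex", "basis")) {
      rel <- d$release[d$batch_id == b & d$region == r]
      expect_equal(sum(rel == "gradual"), sum(rel == "rapid"))
    }
  }
})

test_that("smallest balanced block and input validation behave", {
  d <- build_design(2, 2, seed = 0)
  expect_equal(nrow(d), 4L)
  for (r in c("apex", "basis")) {
    expect_setequal(d$release[d$region == r], c("gradual", "rapid"))
  }
  expect_error(build_design(0, 6), "positive")
  expect_error(build_design(84, -1), "positive")
  expect_warning(build_design(10, 6, seed = 1), "multiple")
})

test_that("designs and full studies are reproducible for a fixed seed", {
  expect_identical(build_design(84, 6, seed = 1), build_design(84, 6, seed = 1))
  expect_identical(simulate_study(seed = 7), simulate_study(seed = 7))
  ## different seeds differ
  expect_false(identical(simulate_study(seed = 7), simulate_study(seed = 8)))
})

test_that("covariate draws match the calibrated per-condition moments", {
  d <- cell_records("apex", "gradual", 10000, seed = 3)
  expect_lt(abs(mean(d$metal_temp) - trunc_norm_mean_ref(-13.8, 8.1)), 0.35)
  expect_lt(abs(mean(d$application_time) - 3.8), 0.1)
  expect_true(all(d$application_time > 0))
  expect_true(all(d$detachment_time > 0))
  expect_true(all(d$metal_temp >= -40 & d$metal_temp <= 2))
  ## the stage-decomposition identity
  expect_equal(d$contact_time, d$application_time + d$detachment_time)
  ## poor quality only at the apex
  s <- simulate_study(seed = 5)
  expect_true(all(!s$poor_quality[s$region == "basis"]))
})

test_that("gradual-minus-rapid gap in detachment stage matches the study", {
  two <- function(release) {
    d <- data.frame(tongue_id = 1:20000, batch_id = 1:20000,
                    region = rep(c("apex", "basis"), 10000),
                    release = release)
    d <- sample_covariates(d, seed = if (release == "gradual") 11 else 12)
    mean(d$contact_time - d$application_time)
  }
  gap <- two("gradual") - two("rapid")
  expect_lt(abs(gap - 1.77), 0.2)
})

test_that("degenerate covariate SDs collapse draws onto the means", {
  p <- generator_params()
  p$covariates$application_sd[] <- 0
  p$covariates$detachment_sd[] <- 0
  p$covariates$metal_temp_sd[] <- 0
  p$tongue_weight_sd <- 0
  p$tongue_temp_sd <- 0
  d <- sample_covariates(build_design(12, 6, seed = 1), p, seed = 2)
  i <- d$region == "apex" & d$release == "gradual"
  expect_true(all(d$application_time[i] == 3.8))
  expect_true(all(d$metal_temp[i] == -13.8))
  expect_true(all(d$tongue_weight == 196.2))
})

test_that("forces reduce to cell means when noise is off and covariates centred", {
  p <- noise_free_params()
  cells <- expand.grid(region = c("apex", "basis"),
                       release = c("gradual", "rapid"),
                       stringsAsFactors = FALSE)
  d <- data.frame(tongue_id = 1:4, batch_id = 1:4,
                  region = cells$region, release = cells$release)
  d$contact_time <- cell_contact_mean_ref(p, d$region, d$release)
  d$application_time <- d$contact_time / 2
  d$detachment_time <- d$contact_time / 2
  d$metal_temp <- cell_metal_temp_mean_ref(p, d$region, d$release)
  d <- simulate_forces(d, p, seed = 1)
  expect_equal(d$peak_force,
               unname(p$cell_mean_force[paste(d$region, d$release,
                                              sep = ".")]))
  expect_error(simulate_forces(transform(d, region = "root"), p, seed = 1),
               "unknown region")
})

test_that("large-sample cell force moments match the calibration targets", {
  br <- cell_records("basis", "rapid", 30000, seed = 21)
  expect_lt(abs(mean(br$peak_force) - 22.6), 1)
  for (cl in list(c("apex", "gradual"), c("apex", "rapid"),
                  c("basis", "gradual"), c("basis", "rapid"))) {
    x <- cell_records(cl[1], cl[2], 8000, seed = 31)
    expect_gt(sd(x$peak_force), 7)
    expect_lt(sd(x$peak_force), 15)
  }
})

test_that("mean force over metal temperature peaks at -7.5 degC", {
  ## grid-search oracle: with noise off and fixed covariates, sweep T
  p <- noise_free_params()
  Tgrid <- seq(-30, 1, by = 0.1)
  d <- data.frame(tongue_id = seq_along(Tgrid), batch_id = seq_along(Tgrid),
                  region = "apex", release = "gradual",
                  contact_time = 7.7, metal_temp = Tgrid)
  d <- simulate_forces(d, p, seed = 1)
  expect_equal(Tgrid[which.max(d$peak_force)], -7.5, tolerance = 1e-8)
})

test_that("outcome models respond to their generator coefficients", {
  ## symmetric logistic null: 50% avulsion
  p0 <- generator_params(gamma0 = 0, gamma1 = 0, sigma_avulsion_re = 0)
  d <- cell_records("apex", "gradual", 20000, seed = 41)
  d <- simulate_outcomes(d, p0, seed = 42)
  expect_lt(abs(mean(d$avulsion) - 0.5), 0.01)
  ## stronger slope => stronger refitted force-avulsion association
  assoc <- function(gamma1) {
    p <- generator_params(gamma1 = gamma1)
    s <- study_2000(31, params = p)
    coef(glm(avulsion ~ scale(peak_force), binomial, data = s))[2]
  }
  expect_gt(assoc(2.0), assoc(0.5))
})

test_that("exclusions drop the right number of records, reproducibly", {
  d <- build_design(84, 6, seed = 1)
  expect_equal(nrow(apply_exclusions(d, 4, seed = 1)), 164L)
  expect_identical(apply_exclusions(d, 4, seed = 9),
                   apply_exclusions(d, 4, seed = 9))
  expect_identical(apply_exclusions(d, 0), d)
  expect_error(apply_exclusions(d, nrow(d)), "n_excluded")
})

test_that("application and contact times are strongly rank-correlated", {
  d <- default_study()
  rs <- cor(d$application_time, d$contact_time, method = "spearman")
  expect_gte(rs, 0.5)
})

test_that("CSV output round-trips with a JSON parameter sidecar", {
  d <- default_study()
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(d, path, generator_params(), seed = 1)
  back <- read_records(path)
  expect_equal(back$peak_force, d$peak_force)
  expect_equal(back$region, d$region)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 1L)
  expect_equal(side$generator$T_peak, -7.5)
})

test_that("generator parameter overrides are validated", {
  expect_equal(generator_params(gamma1 = 0)$gamma1, 0)
  expect_error(generator_params(not_a_param = 1), "unknown generator")
  expect_error(generator_params(kappa = -1))
})
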