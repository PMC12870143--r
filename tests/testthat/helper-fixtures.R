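## Shared fixtures, built once per test run.

tt_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, tt_cache)) assign(key, expr, tt_cache)
  get(key, tt_cache)
}

## Full-design synthetic study (164 analysed records).
default_study <- function(seed = 1) {
  memo(paste0("study", seed), simulate_study(seed = seed))
}

## Records frame for one region x release cell with independent tongues
## (one record per tongue, so random effects are i.i.d. across rows).
cell_records <- function(region, release, n, params = generator_params(),
                         seed = 1) {
  d <- data.frame(tongue_id = seq_len(n), batch_id = seq_len(n),
                  region = region, release = release,
                  stringsAsFactors = FALSE)
  d <- sample_covariates(d, params, seed = seed)
  simulate_forces(d, params, seed = seed + 1)
}

## A 2000-record study (1000 tongues in batches of 4) for recovery tests.
study_2000 <- function(seed, params = generator_params()) {
  simulate_study(n_tongues = 1000L, batch_size = 4L, n_excluded = 0L,
                 params = params, seed = seed)
}

## Zero-noise generator parameters (degenerate covariates keep their means).
noise_free_params <- function() {
  p <- generator_params(sigma_batch = 0, sigma_tongue = 0, sigma_resid = 0)
  p
}

## Independent oracle: mean of a truncated normal by numerical integration.
trunc_norm_mean_ref <- function(mean, sd, lower = -40, upper = 2) {
  z <- integrate(function(x) dnorm(x, mean, sd), lower, upper)$value
  integrate(function(x) x * dnorm(x, mean, sd), lower, upper)$value / z
}

## Cell-level covariate expectations straight from the parameter table.
cell_row <- function(p, region, release) {
  idx <- match(paste(region, release),
               paste(p$covariates$region, p$covariates$release))
  p$covariates[idx, , drop = FALSE]
}

cell_contact_mean_ref <- function(p, region, release) {
  r <- cell_row(p, region, release)
  r$application_mean + r$detachment_mean
}

cell_metal_temp_mean_ref <- function(p, region, release) {
  r <- cell_row(p, region, release)
  mapply(trunc_norm_mean_ref, r$metal_temp_mean, r$metal_temp_sd)
}

## Flat-interface geometry helpers for solver validation.
flat_roughness <- function() {
  list(amplitude = c(0, 0), wavelength = c(4, 10), phase = c(0, 0))
}

## Uniform-property material table (every domain behaves like one solid).
uniform_materials <- function(k = 0.5, rho = 1050, c = 3600, init = 37) {
  m <- material_table()
  m$k[] <- k; m$rho[] <- rho; m$c[] <- c
  m$initial_temp[] <- init
  m
}

## Cached default-geometry scenario fields (vessels off, 7 s horizon).
scenario_field <- function(metal_temp, vessels_active = FALSE,
                           spacing = 0.025, t_end = 7) {
  key <- sprintf("field_%g_%d_%g_%g", metal_temp, vessels_active, spacing,
                 t_end)
  memo(key, simulate_contact(metal_temp, vessels_active = vessels_active,
                             spacing = spacing, t_end = t_end))
}
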