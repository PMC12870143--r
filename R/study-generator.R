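#' Build the block-randomized study design
#'
#' Lays out the detachment experiment: `n_tongues` tongues in slaughter
#' batches of `batch_size`, each tongue contributing one apex and one
#' basis trial.  Within every batch, each region's trials are split as
#' evenly as possible between gradual and rapid release (block
#' randomization), independently for the two regions.
#'
#' @param n_tongues number of tongues (default 84, the full study).
#' @param batch_size tongues per slaughter batch (default 6).  A warning
#'   is issued when `n_tongues` is not a multiple of `batch_size`.
#' @param seed integer seed; the design is reproducible for a fixed seed.
#' @return A data frame with one row per planned trial (`2 * n_tongues`
#'   rows): `tongue_id`, `batch_id`, `region` ("apex"/"basis"), `release`
#'   ("gradual"/"rapid").
#' @examples
#' d <- build_design(84, 6, seed = 1)
#' nrow(d)                      # 168 planned trials
#' table(d$release, d$region)   # balanced
#' @export
build_design <- function(n_tongues = 84L, batch_size = 6L, seed = NULL) {
  if (!is.numeric(n_tongues) || n_tongues < 1 ||
      !is.numeric(batch_size) || batch_size < 1) {
    stop("`n_tongues` and `batch_size` must be positive counts",
         call. = FALSE)
  }
  n_tongues <- as.integer(n_tongues)
  batch_size <- as.integer(batch_size)
  if (n_tongues %% batch_size != 0L) {
    warning("n_tongues is not a multiple of batch_size; last batch is short",
            call. = FALSE)
  }
  tongue_id <- seq_len(n_tongues)
  batch_id <- (tongue_id - 1L) %/% batch_size + 1L
  design <- with_seed(seed, {
    rows <- lapply(c("apex", "basis"), function(region) {
      release <- unlist(lapply(split(tongue_id, batch_id), function(ids) {
        k <- length(ids)
        labs <- rep(c("gradual", "rapid"), length.out = k)
        sample(labs, k)
      }), use.names = FALSE)
      data.frame(tongue_id = tongue_id, batch_id = batch_id,
                 region = region, release = release,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  design <- design[order(design$tongue_id, design$region), ]
  rownames(design) <- NULL
  design
}

#' Draw per-trial covariates
#'
#' Adds the experimental covariates to a design: metal surface
#' temperature (normal truncated to the plausible lamp-post range),
#' application and detachment times (gamma, strictly positive), contact
#' time (their sum, the stage-decomposition identity of the force
#' traces), per-tongue weight and temperature, and the poor-quality flag
#' for apex surfaces damaged during slaughter.
#'
#' @param design data frame from [build_design()] (or any data frame with
#'   `tongue_id`, `region`, `release` columns).
#' @param params a [generator_params()] object.
#' @param seed integer seed.
#' @return The input with columns `metal_temp`, `application_time`,
#'   `detachment_time`, `contact_time`, `tongue_weight`, `tongue_temp`,
#'   `poor_quality` appended.
#' @export
sample_covariates <- function(design, params = generator_params(),
                              seed = NULL) {
  stop_if_not_records(design, c("tongue_id", "region", "release"))
  stopifnot(inherits(params, "tt_generator_params"))
  n <- nrow(design)
  idx <- cell_index(params, design$region, design$release)
  cov <- params$covariates
  with_seed(seed, {
    design$metal_temp <- rtrunc_norm(
      n, cov$metal_temp_mean[idx], cov$metal_temp_sd[idx],
      params$metal_temp_range[1], params$metal_temp_range[2])
    design$application_time <- rgamma_ms(
      n, cov$application_mean[idx], cov$application_sd[idx])
    design$detachment_time <- rgamma_ms(
      n, cov$detachment_mean[idx], cov$detachment_sd[idx])
    design$contact_time <- design$application_time + design$detachment_time
    ## weight is a property of the tongue, shared by its two trials
    tongues <- unique(design$tongue_id)
    w <- rtrunc_norm(length(tongues), params$tongue_weight_mean,
                     params$tongue_weight_sd, lower = 0)
    design$tongue_weight <- w[match(design$tongue_id, tongues)]
    design$tongue_temp <- rtrunc_norm(
      n, params$tongue_temp_mean, params$tongue_temp_sd, lower = 0)
    design$poor_quality <- design$region == "apex" &
      runif(n) < params$p_poor_quality_apex
    design
  })
}

#' Simulate peak detachment forces
#'
#' Peak force for each trial is the cell mean (region x release) plus a
#' contact-time effect, a quadratic metal-temperature effect centred so
#' the cell means are preserved, batch and tongue random intercepts, and
#' residual noise; negative draws are clamped at zero (a force sensor
#' cannot record negative peak tension):
#' \deqn{F = m_{cell} + \beta_c (c - \bar c_{cell}) + q(T) - q(\bar T_{cell})
#'       + u_{batch} + u_{tongue} + \epsilon,\quad
#'       q(T) = -\kappa (T - T_{peak})^2}
#'
#' @param records data frame with design factors and covariates (see
#'   [sample_covariates()]).
#' @param params a [generator_params()] object.
#' @param seed integer seed.
#' @return `records` with a `peak_force` column (N) appended.
#' @export
simulate_forces <- function(records, params = generator_params(),
                            seed = NULL) {
  stop_if_not_records(records, c("tongue_id", "batch_id", "region",
                                 "release", "metal_temp", "contact_time"))
  stopifnot(inherits(params, "tt_generator_params"))
  cell <- paste(records$region, records$release, sep = ".")
  m_cell <- params$cell_mean_force[cell]
  if (anyNA(m_cell)) stop("unknown region/release cell label", call. = FALSE)
  q <- function(T) -params$kappa * (T - params$T_peak)^2
  c_bar <- cell_contact_mean(params, records$region, records$release)
  T_bar <- cell_metal_temp_mean(params, records$region, records$release)
  mu <- unname(m_cell) +
    params$beta_contact * (records$contact_time - c_bar) +
    q(records$metal_temp) - q(T_bar)
  with_seed(seed, {
    batches <- unique(records$batch_id)
    tongues <- unique(records$tongue_id)
    u_b <- rnorm(length(batches), 0, params$sigma_batch)
    u_t <- rnorm(length(tongues), 0, params$sigma_tongue)
    eps <- rnorm(nrow(records), 0, params$sigma_resid)
    records$peak_force <- pmax(
      0, mu + u_b[match(records$batch_id, batches)] +
        u_t[match(records$tongue_id, tongues)] + eps)
    records
  })
}

#' Simulate avulsion and cold-injury outcomes
#'
#' Avulsion follows a random-intercept logistic model on the z-scored
#' peak force (standardised with the dataset's own mean and SD), with a
#' per-tongue normal random intercept.  Macroscopic cold injury follows a
#' logistic model on metal temperature, with colder metal raising the
#' risk.
#'
#' @param records data frame with `peak_force` present.
#' @param params a [generator_params()] object.
#' @param seed integer seed.
#' @return `records` with logical columns `avulsion` and `cold_injury`.
#' @export
simulate_outcomes <- function(records, params = generator_params(),
                              seed = NULL) {
  stop_if_not_records(records, c("tongue_id", "metal_temp", "peak_force"))
  stopifnot(inherits(params, "tt_generator_params"))
  z <- as.numeric(scale(records$peak_force))
  if (anyNA(z)) z <- rep(0, nrow(records))  # zero-variance degenerate case
  with_seed(seed, {
    tongues <- unique(records$tongue_id)
    u <- rnorm(length(tongues), 0, params$sigma_avulsion_re)
    eta_av <- params$gamma0 + params$gamma1 * z +
      u[match(records$tongue_id, tongues)]
    records$avulsion <- runif(nrow(records)) < plogis(eta_av)
    eta_cold <- params$delta0 + params$delta1 * records$metal_temp
    records$cold_injury <- runif(nrow(records)) < plogis(eta_cold)
    records
  })
}

#' Randomly exclude failed experiments
#'
#' Drops `n_excluded` records uniformly at random, mimicking trials lost
#' to experimental error (e.g. the peak force falling outside the
#' sampling window).
#'
#' @param records data frame of trials.
#' @param n_excluded number of records to drop (default 4).
#' @param seed integer seed.
#' @return `records` with `n_excluded` rows removed.
#' @export
apply_exclusions <- function(records, n_excluded = 4L, seed = NULL) {
  stopifnot(is.data.frame(records))
  n_excluded <- as.integer(n_excluded)
  if (n_excluded < 0L || n_excluded >= nrow(records)) {
    stop("`n_excluded` must be in [0, nrow(records))", call. = FALSE)
  }
  if (n_excluded == 0L) return(records)
  drop <- with_seed(seed, sample.int(nrow(records), n_excluded))
  out <- records[-drop, ]
  rownames(out) <- NULL
  out
}

#' Simulate a complete detachment study
#'
#' Convenience wrapper chaining [build_design()], [sample_covariates()],
#' [simulate_forces()], [simulate_outcomes()] and [apply_exclusions()],
#' with independent RNG streams per stage derived from one master seed.
#'
#' @param n_tongues,batch_size,n_excluded study dimensions; defaults are
#'   the full experiment (84 tongues in batches of 6, 4 exclusions).
#' @param params a [generator_params()] object.
#' @param seed master integer seed.
#' @return A data frame of analysed trials
#'   (`2 * n_tongues - n_excluded` rows).
#' @examples
#' d <- simulate_study(seed = 1)
#' nrow(d)            # 164
#' mean(d$avulsion)   # about 0.54
#' @export
simulate_study <- function(n_tongues = 84L, batch_size = 6L,
                           n_excluded = 4L, params = generator_params(),
                           seed = NULL) {
  seeds <- derive_seeds(seed, 5L)
  design <- build_design(n_tongues, batch_size, seed = seeds[[1]])
  records <- sample_covariates(design, params, seed = seeds[[2]])
  records <- simulate_forces(records, params, seed = seeds[[3]])
  records <- simulate_outcomes(records, params, seed = seeds[[4]])
  apply_exclusions(records, n_excluded, seed = seeds[[5]])
}

#' Write a simulated study to CSV with a JSON parameter sidecar
#'
#' @param records data frame of trials.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param params the [generator_params()] the data were drawn from.
#' @param seed the master seed used (recorded in the sidecar).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, params = generator_params(),
                          seed = NULL) {
  utils::write.csv(records, path, row.names = FALSE)
  sidecar <- params
  attributes(sidecar) <- list(names = names(params))
  jsonlite::write_json(
    list(generator = sidecar, seed = seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a simulated study back from CSV
#'
#' @param path CSV path written by [write_records()].
#' @return Data frame of trials.
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
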