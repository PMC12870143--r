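#' Default pipeline configuration
#'
#' @param seed master seed.
#' @param n_tongues,batch_size,n_excluded study dimensions.
#' @param generator named list of [generator_params()] overrides.
#' @param heat_scenarios metal temperatures (degC) to simulate.
#' @param heat_vessels vessel toggles to run per scenario.
#' @param heat_pediatric run the pediatric geometry (in addition to the
#'   adult one)?
#' @param heat_spacing mesh spacing, mm.
#' @param heat_t_end simulated contact time, s.
#' @return Named list, the pipeline configuration.
#' @export
pipeline_config <- function(seed = 1L, n_tongues = 84L, batch_size = 6L,
                            n_excluded = 4L, generator = list(),
                            heat_scenarios = c(-4, -12, -25, -40),
                            heat_vessels = c(TRUE, FALSE),
                            heat_pediatric = FALSE,
                            heat_spacing = 0.025, heat_t_end = 7) {
  if (any(heat_scenarios < -60 | heat_scenarios > 10)) {
    stop("heat-scenario metal temperatures must lie in [-60, 10] degC",
         call. = FALSE)
  }
  list(seed = seed, n_tongues = n_tongues, batch_size = batch_size,
       n_excluded = n_excluded, generator = generator,
       heat_scenarios = heat_scenarios, heat_vessels = heat_vessels,
       heat_pediatric = heat_pediatric, heat_spacing = heat_spacing,
       heat_t_end = heat_t_end)
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field of [pipeline_config()] may be set in the file; unset fields
#' take their defaults.
#'
#' @param path YAML file path.
#' @return Pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full generate-fit-simulate-report pipeline
#'
#' Simulates a detachment study, fits the linear and quadratic force
#' models and compares them, fits the injury-risk models, computes the
#' two-stage avulsion risk surface, runs the requested contact-freezing
#' scenarios, and writes every artefact (dataset CSV, fit JSONs,
#' risk-surface CSV, probe-trace CSVs) plus a `summary.json` echoing the
#' headline quantities.  Every output records the seed and a hash of the
#' configuration; re-running with the same configuration reproduces the
#' outputs.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir output directory (created if missing); `NULL` skips
#'   file output and just returns the bundle.
#' @param quiet suppress per-stage progress messages?
#' @return Invisibly, a list with the dataset, fits, comparison, risk
#'   surface, heat-scenario traces and the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  hash <- config_hash(config)
  params <- do.call(generator_params, config$generator)

  say("generate", "simulating %d tongues (seed %d)", config$n_tongues,
      config$seed)
  records <- simulate_study(config$n_tongues, config$batch_size,
                            config$n_excluded, params,
                            seed = config$seed)

  say("fit", "force models (linear and quadratic, ML)")
  fit_lin <- fit_force_lmm(records, include_quadratic = FALSE)
  fit_quad <- fit_force_lmm(records, include_quadratic = TRUE)
  cmp <- compare_models(fit_lin, fit_quad)
  peak <- tryCatch(peak_temperature(fit_quad), error = function(e) NA_real_)

  say("risk", "avulsion and cold-injury models")
  fit_av <- fit_avulsion_model(records, "force")
  fit_av4 <- fit_avulsion_model(records, "four_var")
  fit_cold <- suppressWarnings(fit_cold_model(records))
  grid <- risk_surface(fit_av, predict_force_grid(fit_quad))

  say("heatsim", "%d metal temperature(s) x %d vessel toggle(s)%s",
      length(config$heat_scenarios), length(config$heat_vessels),
      if (config$heat_pediatric) " (pediatric)" else "")
  scenarios <- expand.grid(metal_temp = config$heat_scenarios,
                           vessels = config$heat_vessels,
                           KEEP.OUT.ATTRS = FALSE)
  heat <- lapply(seq_len(nrow(scenarios)), function(i) {
    field <- simulate_contact(scenarios$metal_temp[i],
                              pediatric = config$heat_pediatric,
                              vessels_active = scenarios$vessels[i],
                              spacing = config$heat_spacing,
                              t_end = config$heat_t_end)
    list(metal_temp = scenarios$metal_temp[i],
         vessels = scenarios$vessels[i],
         damage_point = damage_point_probe(field),
         interface = interface_trace(field),
         freezing_depth_mm = isotherm_depth(field, 0,
                                            config$heat_t_end)$median)
  })

  summary <- list(
    seed = config$seed, config_hash = hash,
    n_records = nrow(records),
    avulsion_rate = mean(records$avulsion),
    cold_injury_rate = mean(records$cold_injury),
    peak_adhesion_temp = peak,
    force_slope_per_sd = unname(fit_av$coefficients["force_z"]),
    odds_increase_percent =
      100 * (exp(unname(fit_av$coefficients["force_z"])) - 1),
    delta_aic = cmp$delta_aic,
    akaike_weight = cmp$akaike_weight_preferred,
    freezing_depths_mm = stats::setNames(
      vapply(heat, `[[`, numeric(1), "freezing_depth_mm"),
      vapply(heat, function(h) sprintf("T%+g_vessels_%s", h$metal_temp,
                                       h$vessels), character(1)))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(records, file.path(out_dir, "records.csv"), params,
                  config$seed)
    fit_json <- function(fit, path) {
      obj <- fit[setdiff(names(fit), "model")]
      obj$seed <- config$seed; obj$config_hash <- hash
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
    fit_json(fit_lin, file.path(out_dir, "fit_force_linear.json"))
    fit_json(fit_quad, file.path(out_dir, "fit_force_quadratic.json"))
    fit_json(fit_av, file.path(out_dir, "fit_avulsion_force.json"))
    fit_json(fit_av4, file.path(out_dir, "fit_avulsion_4var.json"))
    fit_json(fit_cold, file.path(out_dir, "fit_cold.json"))
    utils::write.csv(grid, file.path(out_dir, "risk_surface.csv"),
                     row.names = FALSE)
    for (h in heat) {
      tag <- sprintf("T%+g_vessels_%s", h$metal_temp, h$vessels)
      write_trace(h$damage_point,
                  file.path(out_dir, paste0("damage_point_", tag, ".csv")))
      write_trace(h$interface,
                  file.path(out_dir, paste0("interface_", tag, ".csv")))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(records = records, fit_linear = fit_lin,
                 fit_quadratic = fit_quad, comparison = cmp,
                 fit_avulsion = fit_av, fit_avulsion_4var = fit_av4,
                 fit_cold = fit_cold, risk_surface = grid, heat = heat,
                 summary = summary))
}

#' Generate reference fixtures
#'
#' `"tiny"` is a 12-tongue (24-record) study plus a coarse short
#' contact-freezing scenario for fast checks; `"default"` is the full
#' 84-tongue (168-record) design.  Both are pre-exclusion.
#'
#' @param size `"tiny"` or `"default"`.
#' @param seed fixture seed (fixtures regenerate identically from it).
#' @param out_dir optional directory to write `records.csv` (+ JSON
#'   sidecar) into.
#' @return List with `records` and, for `"tiny"`, a `field` thermal
#'   snapshot bundle.
#' @export
make_fixtures <- function(size = c("tiny", "default"), seed = 42L,
                          out_dir = NULL) {
  size <- match.arg(size)
  if (size == "tiny") {
    records <- simulate_study(n_tongues = 12L, batch_size = 6L,
                              n_excluded = 0L, seed = seed)
    field <- simulate_contact(-12, spacing = 0.035, t_end = 2,
                              vessels_active = FALSE)
  } else {
    records <- simulate_study(n_excluded = 0L, seed = seed)
    field <- NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(records, file.path(out_dir, "records.csv"),
                  generator_params(), seed)
  }
  list(records = records, field = field)
}
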