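#' Simulation configuration for the contact-freezing solver
#'
#' @param metal_initial_temp initial steel temperature, degC (required).
#' @param t_end simulated time, s (default 15).
#' @param dt_output snapshot interval, s (default 0.1; also the internal
#'   implicit time step — longer output intervals are sub-stepped at
#'   0.1 s).
#' @param tissue_initial_temp initial tongue temperature, degC
#'   (default 37).
#' @param saliva_initial_temp initial film temperature, degC
#'   (default 20).
#' @param vessels_active hold vessel cells at 37 degC (Dirichlet
#'   perfusion clamp)?
#' @param freezing_ref_temp isotherm used to diagnose freezing, degC
#'   (default 0; comparable soft tissues freeze around -0.8 to -1.0).
#' @return Object of class `tt_sim_config`.
#' @export
simulation_config <- function(metal_initial_temp,
                              t_end = 15, dt_output = 0.1,
                              tissue_initial_temp = 37.0,
                              saliva_initial_temp = 20.0,
                              vessels_active = TRUE,
                              freezing_ref_temp = 0.0) {
  stopifnot(is.numeric(metal_initial_temp), t_end > 0, dt_output > 0)
  structure(list(metal_initial_temp = metal_initial_temp,
                 t_end = t_end, dt_output = dt_output,
                 tissue_initial_temp = tissue_initial_temp,
                 saliva_initial_temp = saliva_initial_temp,
                 vessels_active = isTRUE(vessels_active),
                 freezing_ref_temp = freezing_ref_temp),
            class = "tt_sim_config")
}

#' Solve transient heat conduction on a rasterized geometry
#'
#' Finite-volume discretisation of \eqn{\rho c \,\partial T/\partial t =
#' \nabla \cdot (k \nabla T)} on the structured mesh, with harmonic-mean
#' face conductivities across material boundaries, a no-flux (closed)
#' outer boundary, and backward-Euler time stepping (unconditionally
#' stable at film-resolving cell sizes).  When `vessels_active`, every
#' cell inside a vessel disc is held at 37 degC, the volumetric analogue
#' of a perfusion Dirichlet condition.  The sparse system matrix is
#' factorised once (Cholesky) and reused for all steps.
#'
#' @param mesh a [rasterize()]d geometry.
#' @param materials a [material_table()].
#' @param config a [simulation_config()].
#' @param dirichlet optional extra temperature clamp for validation
#'   studies: a list with logical matrix `mask` (ny x nx) and scalar (or
#'   matrix) `temp`.
#' @return Object of class `tt_thermal_field`: `times` (s), 3-D array
#'   `temps` (ny x nx x n_times, degC), the `mesh` and `config`.
#' @examples
#' \donttest{
#' mesh <- rasterize(tongue_geometry(), spacing = 0.035)
#' field <- solve_transient(mesh, material_table(),
#'                          simulation_config(-12, t_end = 7))
#' isotherm_depth(field, 0, time = 7)$median
#' }
#' @export
solve_transient <- function(mesh, materials = material_table(),
                            config, dirichlet = NULL) {
  stopifnot(inherits(mesh, "tt_mesh"), inherits(config, "tt_sim_config"))
  ny <- length(mesh$y); nx <- length(mesh$x); N <- ny * nx
  mat_idx <- match(mesh$materials, materials$name)
  if (anyNA(mat_idx)) {
    stop("material table lacks entries for: ",
         paste(mesh$materials[is.na(mat_idx)], collapse = ", "),
         call. = FALSE)
  }
  k_cell <- matrix(materials$k[mat_idx][mesh$label], ny, nx)
  rhoc_cell <- matrix((materials$rho * materials$c)[mat_idx][mesh$label],
                      ny, nx)
  ## vessel cells carry blood properties
  iv <- match("vessel", materials$name)
  if (!is.na(iv) && any(mesh$vessel)) {
    k_cell[mesh$vessel] <- materials$k[iv]
    rhoc_cell[mesh$vessel] <- materials$rho[iv] * materials$c[iv]
  }
  mm <- 1e-3                              # mesh lengths are mm; solve in SI
  dxm <- mesh$dx * mm; dym <- mesh$dy * mm

  ## initial temperatures
  init <- numeric(nrow(materials))
  init[] <- materials$initial_temp
  i_steel <- match("steel", materials$name)
  init[i_steel] <- config$metal_initial_temp
  init[is.na(init)] <- config$tissue_initial_temp
  i_sal <- match("saliva", materials$name)
  init[i_sal] <- config$saliva_initial_temp
  tissue_rows <- match(c("epithelium", "connective", "muscle", "vessel"),
                       materials$name)
  init[stats::na.omit(tissue_rows)] <- config$tissue_initial_temp
  T0 <- matrix(init[mat_idx][mesh$label], ny, nx)
  if (config$vessels_active) T0[mesh$vessel] <- 37.0
  if (!is.null(dirichlet)) T0[dirichlet$mask] <- dirichlet$temp

  ## face conductances (W/K per metre of out-of-plane depth)
  id <- function(i, j) i + (j - 1L) * ny
  iv_ <- rep(seq_len(ny - 1L), nx)
  jv_ <- rep(seq_len(nx), each = ny - 1L)
  a_v <- id(iv_, jv_); b_v <- id(iv_ + 1L, jv_)
  g_v <- dxm[jv_] / (0.5 * dym[iv_] / k_cell[a_v] +
                     0.5 * dym[iv_ + 1L] / k_cell[b_v])
  ih_ <- rep(seq_len(ny), nx - 1L)
  jh_ <- rep(seq_len(nx - 1L), each = ny)
  a_h <- id(ih_, jh_); b_h <- id(ih_, jh_ + 1L)
  g_h <- dym[ih_] / (0.5 * dxm[jh_] / k_cell[a_h] +
                     0.5 * dxm[jh_ + 1L] / k_cell[b_h])
  ia <- c(a_v, a_h); ib <- c(b_v, b_h); g <- c(g_v, g_h)
  W <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = c(g, g),
                            dims = c(N, N))
  L <- Matrix::Diagonal(N, Matrix::rowSums(W)) - W

  cap <- as.vector(rhoc_cell) * rep(dym, nx) * rep(dxm, each = ny)

  clamped <- as.vector(if (config$vessels_active) mesh$vessel
                       else matrix(FALSE, ny, nx))
  if (!is.null(dirichlet)) clamped <- clamped | as.vector(dirichlet$mask)
  free <- which(!clamped)

  n_sub <- max(1L, as.integer(ceiling(config$dt_output / 0.1 - 1e-9)))
  dt <- config$dt_output / n_sub
  times <- seq(0, config$t_end, by = config$dt_output)
  n_out <- length(times)
  temps <- array(NA_real_, dim = c(ny, nx, n_out))
  temps[, , 1] <- T0

  M <- Matrix::Diagonal(N, cap / dt) + L
  M_ff <- M[free, free, drop = FALSE]
  ch <- Matrix::Cholesky(methods::as(M_ff, "symmetricMatrix"), LDL = FALSE)
  W_fc <- W[free, clamped, drop = FALSE]
  Tc <- as.vector(T0)[clamped]
  bc_term <- if (length(Tc)) as.numeric(W_fc %*% Tc) else 0

  Tv <- as.vector(T0)
  for (s in seq_len(n_out - 1L)) {
    for (sub in seq_len(n_sub)) {
      rhs <- cap[free] / dt * Tv[free] + bc_term
      sol <- Matrix::solve(ch, rhs, system = "A")
      Tv[free] <- as.numeric(sol)
    }
    temps[, , s + 1L] <- Tv
  }
  structure(list(times = times, temps = temps, mesh = mesh,
                 config = config, capacity = cap, clamped = clamped),
            class = "tt_thermal_field")
}

#' @export
print.tt_thermal_field <- function(x, ...) {
  cat(sprintf("Thermal field: %d snapshots over %g s on a %d x %d mesh\n",
              length(x$times), max(x$times), dim(x$temps)[1],
              dim(x$temps)[2]))
  cat(sprintf("  metal initial %g degC; vessels %s\n",
              x$config$metal_initial_temp,
              if (x$config$vessels_active) "active (37 degC clamp)"
              else "inactive"))
  cat(sprintf("  final temperature range [%.1f, %.1f] degC\n",
              min(x$temps[, , dim(x$temps)[3]]),
              max(x$temps[, , dim(x$temps)[3]])))
  invisible(x)
}

#' Total enthalpy of each stored snapshot
#'
#' \eqn{\sum_i \rho_i c_i T_i V_i} over all cells; constant in time for
#' a closed (no clamp) run, which is the solver's conservation check.
#'
#' @param field a [solve_transient()] result.
#' @return Numeric vector, one value per snapshot (J per metre of
#'   out-of-plane depth).
#' @export
total_enthalpy <- function(field) {
  stopifnot(inherits(field, "tt_thermal_field"))
  apply(field$temps, 3, function(Tm) sum(field$capacity * as.vector(Tm)))
}

#' Simulate one contact-freezing scenario
#'
#' Convenience wrapper: build the (adult or pediatric) geometry,
#' rasterize, and solve for a given metal temperature.
#'
#' @param metal_temp initial steel temperature, degC.
#' @param pediatric use the pediatric geometry?
#' @param vessels_active hold vessels at 37 degC?
#' @param spacing mesh spacing, mm (see [rasterize()]).
#' @param t_end simulated time, s.
#' @param materials a [material_table()].
#' @param ... further arguments to [tongue_geometry()].
#' @return A `tt_thermal_field`.
#' @export
simulate_contact <- function(metal_temp, pediatric = FALSE,
                             vessels_active = TRUE, spacing = 0.025,
                             t_end = 15, materials = material_table(),
                             ...) {
  geo <- tongue_geometry(pediatric = pediatric, ...)
  mesh <- rasterize(geo, spacing = spacing)
  solve_transient(mesh, materials,
                  simulation_config(metal_temp, t_end = t_end,
                                    vessels_active = vessels_active))
}
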