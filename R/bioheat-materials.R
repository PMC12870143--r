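#' Thermophysical material properties for the contact-freezing model
#'
#' Literature defaults for the layered tongue-saliva-metal domain:
#' structural steel for the lamp-post wall, water for the saliva film,
#' and soft-tissue values for the epithelium, lamina propria (connective
#' tissue), muscle/fat bulk and blood-vessel regions.  All values are SI
#' (W/m/K, kg/m^3, J/kg/K) and individually overridable.
#'
#' @param overrides optional named list of lists, e.g.
#'   `list(saliva = list(k = 0.55))`, patching any property of any
#'   material.
#' @return Data frame with columns `name`, `k`, `rho`, `c`,
#'   `initial_temp` (degC; `NA` for steel, whose initial temperature is
#'   the scenario's metal temperature).
#' @examples
#' material_table()
#' material_table(list(muscle = list(k = 0.55)))
#' @export
material_table <- function(overrides = NULL) {
  tab <- data.frame(
    name = c("steel", "saliva", "epithelium", "connective", "muscle",
             "vessel", "air"),
    k   = c(44.5, 0.60, 0.40, 0.45, 0.50, 0.52, 0.026),
    rho = c(7850, 1000, 1100, 1050, 1050, 1060, 1.2),
    c   = c(475, 4186, 3400, 3600, 3700, 3600, 1005),
    initial_temp = c(NA, 20, 37, 37, 37, 37, 24),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, tab$name)
      if (is.na(i)) stop("unknown material: ", nm, call. = FALSE)
      for (prop in names(overrides[[nm]])) {
        if (!prop %in% c("k", "rho", "c", "initial_temp")) {
          stop("unknown material property: ", prop, call. = FALSE)
        }
        tab[[prop]][i] <- overrides[[nm]][[prop]]
      }
    }
  }
  if (any(tab$k <= 0 | tab$rho <= 0 | tab$c <= 0)) {
    stop("conductivity, density and specific heat must be positive",
         call. = FALSE)
  }
  tab
}

#' Thermal effusivity
#'
#' \eqn{e = \sqrt{k \rho c}}, the property governing the instantaneous
#' temperature of two semi-infinite bodies brought into contact.
#'
#' @param k conductivity (W/m/K), `rho` density (kg/m^3), `c` specific
#'   heat (J/kg/K).
#' @param rho,c see `k`.
#' @return Effusivity in SI units (W s^0.5 / m^2 / K).
#' @export
effusivity <- function(k, rho, c) {
  stopifnot(all(k > 0), all(rho > 0), all(c > 0))
  sqrt(k * rho * c)
}

#' Contact temperature of two semi-infinite media
#'
#' When two semi-infinite bodies at temperatures `T1`, `T2` with
#' effusivities `e1`, `e2` touch, the interface immediately assumes the
#' effusivity-weighted mean \eqn{(e_1 T_1 + e_2 T_2)/(e_1 + e_2)} and
#' holds it while both bodies remain effectively semi-infinite.  Used as
#' a closed-form validation oracle for the transient solver.
#'
#' @param e1,T1 effusivity and initial temperature of the first body.
#' @param e2,T2 effusivity and initial temperature of the second body.
#' @return Contact temperature (degC).
#' @examples
#' contact_temperature(1, -15, 1, 37)   # 11: plain average
#' @export
contact_temperature <- function(e1, T1, e2, T2) {
  stopifnot(all(e1 > 0), all(e2 > 0))
  (e1 * T1 + e2 * T2) / (e1 + e2)
}
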