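#' Parametric layered tongue-saliva-metal geometry
#'
#' Builds the 2D cross-section used by the contact-freezing simulator:
#' a flat metal slab, a thin saliva film, then epithelium, connective
#' tissue (lamina propria) and a muscle/fat bulk, with the deeper tissue
#' interfaces perturbed sinusoidally (\eqn{y_i(x) = d_i + A_i
#' \sin(2\pi x/\lambda_i + \phi_i)}) to emulate interface roughness, and
#' circular blood-vessel cross-sections inside the connective and muscle
#' layers.  The contact plane is flat (the metal conforms to a plane,
#' not to the tongue): depth `y` is measured from the saliva-epithelium
#' interface, positive into the tissue, so the metal occupies negative
#' `y` beyond the film.
#'
#' The pediatric variant scales the tissue-layer thicknesses (and their
#' roughness amplitudes) by `pediatric_scale`, leaving the number and
#' size of vessels unchanged.
#'
#' @param width tongue contact-patch width along the surface, mm.
#' @param metal_thickness steel wall thickness, mm (default 4.6).
#' @param metal_overhang lateral extension of the metal wall beyond each
#'   side of the contact patch, mm (default 40).  The lamp-post wall is
#'   much wider than the contact patch and resupplies cold laterally
#'   (in-plane diffusion length in steel is about 9 mm over 7 s); with
#'   no overhang the thin closed slab under the patch warms by several
#'   kelvin within seconds.  The region above the overhang is air.
#' @param saliva_thickness film thickness, mm (default 0.07, the
#'   midpoint of the plausible 0.04-0.1 mm range).
#' @param epithelium_thickness,connective_thickness,muscle_thickness
#'   mean tissue-layer thicknesses, mm.
#' @param roughness list with `amplitude` (mm), `wavelength` (mm),
#'   `phase` (rad), each length 2: epithelium-connective then
#'   connective-muscle interface.
#' @param vessels data frame with columns `x`, `y` (centre, mm; `y` is
#'   depth) and `r` (radius, mm), or `NULL` for none.
#' @param pediatric scale tissue thicknesses down for a child's tongue?
#' @param pediatric_scale thickness factor when `pediatric` (default
#'   0.7, a 30\% reduction).
#' @return Object of class `tt_geometry` with the interface curve
#'   functions and validated dimensions.
#' @examples
#' g <- tongue_geometry()
#' g$interfaces$epithelium_connective(c(0, 5, 10))
#' tongue_geometry(pediatric = TRUE)$epithelium_thickness   # 0.35
#' @export
tongue_geometry <- function(width = 20,
                            metal_thickness = 4.6,
                            metal_overhang = 40,
                            saliva_thickness = 0.07,
                            epithelium_thickness = 0.45,
                            connective_thickness = 1.5,
                            muscle_thickness = 8.0,
                            roughness = list(amplitude = c(0.1, 0.3),
                                             wavelength = c(4, 10),
                                             phase = c(0, 1)),
                            vessels = default_vessels(),
                            pediatric = FALSE,
                            pediatric_scale = 0.7) {
  stopifnot(width > 0, metal_thickness > 0, metal_overhang >= 0,
            saliva_thickness > 0,
            epithelium_thickness > 0, connective_thickness > 0,
            muscle_thickness > 0, pediatric_scale > 0)
  if (pediatric) {
    epithelium_thickness <- epithelium_thickness * pediatric_scale
    connective_thickness <- connective_thickness * pediatric_scale
    muscle_thickness <- muscle_thickness * pediatric_scale
    roughness$amplitude <- roughness$amplitude * pediatric_scale
  }
  A <- roughness$amplitude
  lam <- roughness$wavelength
  phi <- roughness$phase
  stopifnot(length(A) == 2, length(lam) == 2, length(phi) == 2,
            all(A >= 0), all(lam > 0))
  if (A[1] >= min(epithelium_thickness, connective_thickness) / 2 ||
      A[2] >= min(connective_thickness, muscle_thickness) / 2) {
    stop("interface roughness amplitude must be below half the thinner ",
         "adjacent layer thickness", call. = FALSE)
  }
  d_ec <- epithelium_thickness
  d_cm <- epithelium_thickness + connective_thickness
  depth <- d_cm + muscle_thickness
  y_ec <- function(x) d_ec + A[1] * sin(2 * pi * x / lam[1] + phi[1])
  y_cm <- function(x) d_cm + A[2] * sin(2 * pi * x / lam[2] + phi[2])
  ## layers must stay ordered everywhere
  xs <- seq(0, width, length.out = 1000L)
  if (any(y_ec(xs) <= 0) || any(y_cm(xs) <= y_ec(xs)) ||
      any(y_cm(xs) >= depth)) {
    stop("tissue layers overlap; reduce roughness or increase thicknesses",
         call. = FALSE)
  }
  if (!is.null(vessels) && nrow(vessels)) {
    stopifnot(all(c("x", "y", "r") %in% names(vessels)), all(vessels$r > 0))
    ok <- vessels$y - vessels$r > vapply(vessels$x, y_ec, numeric(1)) &
      vessels$y + vessels$r < depth &
      vessels$x - vessels$r > 0 & vessels$x + vessels$r < width
    if (!all(ok)) {
      stop("vessels must lie strictly inside the connective/muscle tissue",
           call. = FALSE)
    }
  }
  structure(list(
    width = width,
    metal_thickness = metal_thickness,
    metal_overhang = metal_overhang,
    saliva_thickness = saliva_thickness,
    epithelium_thickness = epithelium_thickness,
    connective_thickness = connective_thickness,
    muscle_thickness = muscle_thickness,
    tissue_depth = depth,
    roughness = roughness,
    interfaces = list(
      saliva_epithelium = function(x) rep(0, length(x)),
      epithelium_connective = y_ec,
      connective_muscle = y_cm
    ),
    vessels = vessels,
    pediatric = pediatric
  ), class = "tt_geometry")
}

#' Default blood-vessel layout
#'
#' Four vessel cross-sections at 2.5-5 mm depth in the connective and
#' muscle layers.
#'
#' @return Data frame with `x`, `y`, `r` in mm.
#' @export
default_vessels <- function() {
  data.frame(x = c(3, 8, 13, 17),
             y = c(2.5, 4.0, 3.0, 5.0),
             r = c(0.35, 0.5, 0.4, 0.5))
}

#' @export
print.tt_geometry <- function(x, ...) {
  cat(sprintf("Tongue-saliva-metal cross-section, %g mm wide%s\n", x$width,
              if (x$pediatric) " (pediatric)" else ""))
  cat(sprintf("  metal %.2f mm | saliva %.3f mm | epithelium %.2f mm | connective %.2f mm | muscle %.2f mm\n",
              x$metal_thickness, x$saliva_thickness, x$epithelium_thickness,
              x$connective_thickness, x$muscle_thickness))
  nv <- if (is.null(x$vessels)) 0L else nrow(x$vessels)
  cat(sprintf("  %d vessel(s); interface roughness amplitudes %s mm\n", nv,
              paste(x$roughness$amplitude, collapse = "/")))
  invisible(x)
}

#' Rasterize a geometry onto a graded tensor-product mesh
#'
#' Builds a structured finite-volume mesh: uniform in `x`, graded in
#' depth (fine through the saliva film and epithelium, coarsening into
#' the muscle and the metal).  Every cell is labelled with exactly one
#' material by its centre; cells inside vessel discs are flagged.
#'
#' @param geometry a [tongue_geometry()].
#' @param spacing near-surface target cell size in mm (default 0.025).
#'   All zone spacings scale with it (connective 2x, muscle and metal
#'   10x, x-direction 20x), so halving `spacing` refines the whole mesh
#'   twofold.  Must be at most half the saliva film thickness so the
#'   film is resolved by at least two cells.
#' @return Object of class `tt_mesh`: cell-centre coordinate vectors
#'   `x`, `y` (mm; `y` is depth, negative in film and metal), cell sizes
#'   `dx`, `dy`, integer `label` matrix (ny x nx) with a `materials`
#'   level vector, logical `vessel` matrix, and the geometry.
#' @examples
#' m <- rasterize(tongue_geometry(), spacing = 0.035)
#' table(m$materials[m$label])
#' @export
rasterize <- function(geometry, spacing = 0.025) {
  stopifnot(inherits(geometry, "tt_geometry"), spacing > 0)
  g <- geometry
  if (spacing > g$saliva_thickness / 2) {
    stop(sprintf(
      "spacing %.3g mm leaves the %.3g mm saliva film with fewer than 2 cells; use spacing <= %.3g mm",
      spacing, g$saliva_thickness, g$saliva_thickness / 2), call. = FALSE)
  }
  zone_edges <- function(y0, y1, h) {
    n <- max(1L, as.integer(ceiling((y1 - y0) / h - 1e-9)))
    seq(y0, y1, length.out = n + 1L)
  }
  ## depth grid: metal | saliva | epithelium (+ roughness) | connective | muscle
  e_top <- -(g$saliva_thickness + g$metal_thickness)
  A <- g$roughness$amplitude
  z_fine <- g$epithelium_thickness + A[1]        # everything above: fine
  z_mid <- g$epithelium_thickness + g$connective_thickness + A[2]
  edges_y <- c(
    zone_edges(e_top, -g$saliva_thickness, 10 * spacing),
    zone_edges(-g$saliva_thickness, 0, spacing)[-1],
    zone_edges(0, z_fine, spacing)[-1],
    zone_edges(z_fine, z_mid, 2 * spacing)[-1],
    zone_edges(z_mid, g$tissue_depth, 10 * spacing)[-1]
  )
  ov <- g$metal_overhang
  edges_x <- zone_edges(0, g$width, 20 * spacing)
  if (ov > 0) {
    edges_x <- c(rev(zone_edges(0, -ov, -80 * spacing)),
                 edges_x[-1],
                 zone_edges(g$width, g$width + ov, 80 * spacing)[-1])
  }
  yc <- (edges_y[-1] + edges_y[-length(edges_y)]) / 2
  xc <- (edges_x[-1] + edges_x[-length(edges_x)]) / 2
  dy <- diff(edges_y)
  dx <- diff(edges_x)
  ny <- length(yc); nx <- length(xc)

  materials <- c("steel", "saliva", "epithelium", "connective", "muscle",
                 "air")
  label <- matrix(0L, ny, nx)
  in_metal <- yc < -g$saliva_thickness
  in_saliva <- !in_metal & yc < 0
  under_patch <- xc >= 0 & xc <= g$width
  y_ec <- g$interfaces$epithelium_connective(xc)
  y_cm <- g$interfaces$connective_muscle(xc)
  for (j in seq_len(nx)) {
    lab <- integer(ny)
    lab[in_metal] <- 1L
    if (under_patch[j]) {
      lab[in_saliva] <- 2L
      tis <- yc >= 0
      lab[tis & yc < y_ec[j]] <- 3L
      lab[tis & yc >= y_ec[j] & yc < y_cm[j]] <- 4L
      lab[tis & yc >= y_cm[j]] <- 5L
    } else {
      lab[!in_metal] <- 6L               # air above the overhang
    }
    label[, j] <- lab
  }
  vessel <- matrix(FALSE, ny, nx)
  if (!is.null(g$vessels) && nrow(g$vessels)) {
    for (v in seq_len(nrow(g$vessels))) {
      dx2 <- outer(rep(1, ny), (xc - g$vessels$x[v])^2)
      dy2 <- outer((yc - g$vessels$y[v])^2, rep(1, nx))
      vessel <- vessel | (dx2 + dy2 < g$vessels$r[v]^2)
    }
    vessel[label <= 2L] <- FALSE   # vessels live in tissue only
  }
  structure(list(x = xc, y = yc, dx = dx, dy = dy,
                 edges_x = edges_x, edges_y = edges_y,
                 label = label, materials = materials,
                 vessel = vessel, geometry = g, spacing = spacing),
            class = "tt_mesh")
}

#' @export
print.tt_mesh <- function(x, ...) {
  cat(sprintf("Structured mesh: %d x %d cells (%d total), near-surface spacing %g mm\n",
              length(x$y), length(x$x), length(x$y) * length(x$x),
              x$spacing))
  counts <- table(factor(x$materials[x$label], levels = x$materials))
  cat("  cells per material:",
      paste(sprintf("%s %d", names(counts), counts), collapse = ", "), "\n")
  cat(sprintf("  %d vessel-flagged cells\n", sum(x$vessel)))
  invisible(x)
}
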