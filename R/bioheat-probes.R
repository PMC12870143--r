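## Bilinear interpolation of one snapshot at arbitrary (x, y) points on
## the (non-uniform) cell-centre grid; clamped at the domain edge.
interp_field <- function(Tm, mesh, xq, yq) {
  xs <- mesh$x; ys <- mesh$y
  jx <- findInterval(xq, xs, all.inside = TRUE)
  iy <- findInterval(yq, ys, all.inside = TRUE)
  x0 <- xs[jx]; x1 <- xs[jx + 1L]
  y0 <- ys[iy]; y1 <- ys[iy + 1L]
  tx <- pmin(1, pmax(0, (xq - x0) / (x1 - x0)))
  ty <- pmin(1, pmax(0, (yq - y0) / (y1 - y0)))
  T00 <- Tm[cbind(iy, jx)];      T10 <- Tm[cbind(iy, jx + 1L)]
  T01 <- Tm[cbind(iy + 1L, jx)]; T11 <- Tm[cbind(iy + 1L, jx + 1L)]
  (1 - ty) * ((1 - tx) * T00 + tx * T10) +
    ty * ((1 - tx) * T01 + tx * T11)
}

nearest_time_index <- function(field, time) {
  if (time < min(field$times) - 1e-9 || time > max(field$times) + 1e-9) {
    stop("requested time outside the simulated horizon", call. = FALSE)
  }
  which.min(abs(field$times - time))
}

summarize_curve <- function(field, xq, yq) {
  nt <- length(field$times)
  out <- data.frame(time = field$times, median = NA_real_, p10 = NA_real_,
                    p90 = NA_real_, min = NA_real_, max = NA_real_)
  for (s in seq_len(nt)) {
    v <- interp_field(field$temps[, , s], field$mesh, xq, yq)
    q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE)
    out$median[s] <- q[2]; out$p10[s] <- q[1]; out$p90[s] <- q[3]
    out$min[s] <- min(v); out$max[s] <- max(v)
  }
  out
}

#' Freezing-front depth below the tissue surface
#'
#' For the snapshot nearest `time`, finds in every mesh column the
#' deepest tissue cell at or below `threshold_temp`, measured from the
#' saliva-epithelium interface (depth 0).  Columns where no tissue cell
#' is that cold report depth 0.
#'
#' @param field a [solve_transient()] result.
#' @param threshold_temp isotherm temperature, degC (default 0).
#' @param time time of interest, s (snapped to the nearest snapshot).
#' @return List with `median` and `max` over columns (mm), the
#'   `per_column` vector, and the snapshot `time` used.
#' @export
isotherm_depth <- function(field, threshold_temp = 0, time) {
  stopifnot(inherits(field, "tt_thermal_field"))
  s <- nearest_time_index(field, time)
  Tm <- field$temps[, , s]
  tissue <- field$mesh$label >= 3L & field$mesh$label <= 5L
  y <- field$mesh$y
  cols <- which(colSums(tissue) > 0)    # tongue columns only, not overhang
  per_column <- apply(tissue[, cols, drop = FALSE] &
                        Tm[, cols, drop = FALSE] <= threshold_temp, 2,
                      function(hit) if (any(hit)) max(y[hit]) else 0)
  list(median = stats::median(per_column), max = max(per_column),
       per_column = per_column, time = field$times[s])
}

#' Temperature trace along a tissue interface
#'
#' Samples the temperature at `n_points` locations along one of the
#' (possibly rough) interface curves and summarises it per snapshot as
#' median, 10th/90th percentile, min and max — the ribbon view of the
#' interface cooling histories.
#'
#' @param field a [solve_transient()] result.
#' @param geometry the [tongue_geometry()] the field was solved on
#'   (defaults to the one stored in the mesh).
#' @param interface_id one of `"saliva_epithelium"`,
#'   `"epithelium_connective"`, `"connective_muscle"`.
#' @param n_points number of sample points along the curve (>= 50).
#' @return Object of class `tt_trace`: data frame with columns `time`,
#'   `median`, `p10`, `p90`, `min`, `max`.
#' @export
interface_trace <- function(field, geometry = field$mesh$geometry,
                            interface_id = "epithelium_connective",
                            n_points = 101L) {
  stopifnot(inherits(field, "tt_thermal_field"),
            inherits(geometry, "tt_geometry"))
  curve <- geometry$interfaces[[interface_id]]
  if (is.null(curve)) {
    stop("unknown interface: ", interface_id, "; available: ",
         paste(names(geometry$interfaces), collapse = ", "), call. = FALSE)
  }
  n_points <- max(50L, as.integer(n_points))
  xq <- seq(0, geometry$width, length.out = n_points)
  out <- summarize_curve(field, xq, curve(xq))
  attr(out, "interface") <- interface_id
  class(out) <- c("tt_trace", class(out))
  out
}

#' Temperature trace at the histological damage depth
#'
#' Probes a horizontal line at a given fraction of the local epithelium
#' thickness below the tissue surface — by default mid-epithelium
#' (fraction 0.5), the depth where avulsion injuries sit on histology.
#' `fraction` near 0 reproduces the tissue contact-surface trace.
#'
#' @param field a [solve_transient()] result.
#' @param geometry the [tongue_geometry()] (defaults to the mesh's).
#' @param fraction depth as a fraction of local epithelium thickness,
#'   in (0, 1); default 0.5.
#' @param n_points sample points along the line (>= 50).
#' @return Object of class `tt_trace` (see [interface_trace()]).
#' @export
damage_point_probe <- function(field, geometry = field$mesh$geometry,
                               fraction = 0.5, n_points = 101L) {
  stopifnot(inherits(field, "tt_thermal_field"),
            inherits(geometry, "tt_geometry"),
            fraction > 0, fraction < 1)
  n_points <- max(50L, as.integer(n_points))
  xq <- seq(0, geometry$width, length.out = n_points)
  surface <- geometry$interfaces$saliva_epithelium(xq)
  thickness <- geometry$interfaces$epithelium_connective(xq) - surface
  out <- summarize_curve(field, xq, surface + fraction * thickness)
  attr(out, "interface") <- sprintf("damage point (%.0f%% of epithelium)",
                                    100 * fraction)
  class(out) <- c("tt_trace", class(out))
  out
}

#' @export
print.tt_trace <- function(x, ...) {
  cat(sprintf("Temperature trace along %s (%d snapshots)\n",
              attr(x, "interface"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Write a probe trace to CSV
#'
#' @param trace a `tt_trace` from [interface_trace()] or
#'   [damage_point_probe()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
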