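## Geometry-aware metric extraction: the derived circumpapillary circle
## scan, the macular window average, and the rotation of scans into a
## common fovea-to-disc frame.

#' Degrees of visual angle to retinal millimetres
#'
#' Uses the adopted retinal scale of 0.288 mm per degree (so 0.5 degrees
#' is about 0.14 mm).
#'
#' @param deg Visual angle in degrees.
#' @param mm_per_deg Retinal scale; configurable constant.
#' @return Millimetres on the retina.
#' @export
deg_to_mm <- function(deg, mm_per_deg = 0.288) {
  stopifnot(all(is.finite(deg)))
  deg * mm_per_deg
}

#' Derived circumpapillary circle profile
#'
#' Interpolates the thickness map along a circle (default diameter
#' 3.45 mm) centred on the optic disc, emulating the "derived B-scan" of a
#' widefield volume. Samples are ordered in the TSNIT convention
#' (temporal, superior, nasal, inferior, temporal), which sweeps
#' counter-clockwise in screen coordinates for a right eye.
#'
#' @param map A [thickness_map()] (layer RNFL).
#' @param centre Disc centre, mm.
#' @param diameter_mm Circle diameter.
#' @param n_samples Number of equally spaced angular samples (>= 64).
#' @param side `"OD"` or `"OS"` (sets the TSNIT sweep direction).
#' @return An object of class `circle_profile`: `thickness` (um),
#'   `angle_deg` (TSNIT), `diameter_mm`, `centre`, `side`.
#' @export
derive_circle_profile <- function(map, centre, diameter_mm = 3.45,
                                  n_samples = 256, side = c("OD", "OS")) {
  side <- match.arg(side)
  stopifnot(inherits(map, "thickness_map"), length(centre) == 2L,
            diameter_mm > 0)
  if (n_samples < 64) stop("n_samples must be >= 64")
  theta <- (seq_len(n_samples) - 1) * 360 / n_samples
  phi <- tsnit_to_geom(theta, side) * pi / 180
  xs <- centre[1] + diameter_mm / 2 * cos(phi)
  ys <- centre[2] + diameter_mm / 2 * sin(phi)
  lo <- map$origin_mm; hi <- map$origin_mm + map$extent_mm
  out <- xs < lo[1] | xs > hi[1] | ys < lo[2] | ys > hi[2]
  vals <- map_value(map, xs, ys)
  bad <- out | !is.finite(vals)
  if (any(bad))
    stop(sprintf(
      "circle leaves map support over TSNIT arc [%.1f, %.1f] deg",
      min(theta[bad]), max(theta[bad])))
  structure(list(thickness = vals, angle_deg = theta,
                 diameter_mm = diameter_mm, centre = as.numeric(centre),
                 side = side),
            class = "circle_profile")
}

#' @export
print.circle_profile <- function(x, ...) {
  cat(sprintf("<circle_profile> %d samples, diameter %.2f mm, %s\n",
              length(x$thickness), x$diameter_mm, x$side))
  cat(sprintf("  mean %.1f um, range %.1f - %.1f um\n",
              mean(x$thickness), min(x$thickness), max(x$thickness)))
  invisible(x)
}

#' @export
plot.circle_profile <- function(x, ...) {
  graphics::plot(x$angle_deg, x$thickness, type = "l",
                 xlab = "TSNIT angle (deg)", ylab = "thickness (um)",
                 main = "Derived circle scan", ...)
  graphics::axis(1, at = c(0, 90, 180, 270, 360),
                 labels = c("T", "S", "N", "I", "T"), line = 1, tick = FALSE)
  invisible(x)
}

#' Global circumpapillary RNFL thickness (G_ONH)
#'
#' The arithmetic mean of the derived circle-scan samples.
#'
#' @param profile A [derive_circle_profile()] result.
#' @return Mean thickness in um.
#' @export
g_onh <- function(profile) {
  stopifnot(inherits(profile, "circle_profile"))
  mean(profile$thickness)
}

#' Global macular RGCLP thickness (G_mac)
#'
#' Mean of all pixels whose centres fall in the half-open square window
#' (default 6 x 6 mm) centred on the fovea. Pixels flagged missing (NA,
#' e.g. rotated out of support) are excluded from the mean.
#'
#' @param map A [thickness_map()] (layer RGCLP).
#' @param fovea_centre Window centre, mm.
#' @param window_mm Window side length.
#' @return Mean thickness in um.
#' @export
g_mac <- function(map, fovea_centre, window_mm = 6) {
  stopifnot(inherits(map, "thickness_map"), length(fovea_centre) == 2L)
  h <- window_mm / 2
  lo <- fovea_centre - h; hi <- fovea_centre + h
  eps <- 1e-9
  if (lo[1] < map$origin_mm[1] - eps || lo[2] < map$origin_mm[2] - eps ||
      hi[1] > map$origin_mm[1] + map$extent_mm[1] + eps ||
      hi[2] > map$origin_mm[2] + map$extent_mm[2] + eps)
    stop("macular window leaves map support")
  ax <- map_axes(map)
  ix <- which(ax$x >= lo[1] & ax$x < hi[1])
  iy <- which(ax$y >= lo[2] & ax$y < hi[2])
  mean(map$values[ix, iy], na.rm = TRUE)
}

#' Rotate a scan to the common fovea-to-disc angle
#'
#' Resamples the map (bilinear) after rotating about the fovea-disc
#' midpoint so that the fovea-to-disc axis makes `canonical_angle` with
#' the horizontal — the registration step that removes head/eye torsion
#' before cross-eye comparison. Input is expected in OD convention
#' (mirror OS scans first). Pixels whose pre-image falls outside the
#' original support become `NA` and are excluded from downstream means.
#'
#' @param map A [thickness_map()].
#' @param geometry The eye's [eye_geometry()] (OD convention).
#' @param canonical_angle Target axis angle in degrees (default -7).
#' @return The rotated [thickness_map()] on the same grid, with the
#'   rotated geometry attached as attribute `"geometry"`.
#' @export
rotate_to_common_axis <- function(map, geometry, canonical_angle = -7) {
  stopifnot(inherits(map, "thickness_map"), inherits(geometry, "eye_geometry"))
  v <- geometry$disc_centre - geometry$fovea_centre
  current <- atan2(v[2], v[1]) * 180 / pi
  delta <- (canonical_angle - current) * pi / 180
  mid <- (geometry$disc_centre + geometry$fovea_centre) / 2
  rot <- function(p, a) {
    c(cos(a) * p[1] - sin(a) * p[2], sin(a) * p[1] + cos(a) * p[2])
  }
  ax <- map_axes(map)
  gx <- matrix(ax$x, length(ax$x), length(ax$y)) - mid[1]
  gy <- matrix(ax$y, length(ax$x), length(ax$y), byrow = TRUE) - mid[2]
  # pre-image under the inverse rotation
  ca <- cos(-delta); sa <- sin(-delta)
  qx <- mid[1] + ca * gx - sa * gy
  qy <- mid[2] + sa * gx + ca * gy
  vals <- matrix(map_value(map, as.vector(qx), as.vector(qy)),
                 nrow(map$values))
  out <- thickness_map(pmax(vals, 0), map$spacing_mm, map$origin_mm, map$layer)
  out$values[!is.finite(vals)] <- NA_real_
  geom_rot <- eye_geometry(
    mid + rot(geometry$disc_centre - mid, delta),
    mid + rot(geometry$fovea_centre - mid, delta),
    canonical_angle, geometry$side)
  # the scan is unusable if its anchor structure left the support entirely
  anchor <- if (map$layer == "RNFL") geom_rot$disc_centre else geom_rot$fovea_centre
  lo <- map$origin_mm; hi <- map$origin_mm + map$extent_mm
  if (anchor[1] < lo[1] || anchor[1] > hi[1] ||
      anchor[2] < lo[2] || anchor[2] > hi[2])
    stop("rotation moved the measurement region out of map support")
  attr(out, "geometry") <- geom_rot
  out
}
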