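## Phantom generator: eye geometry, parameter container, noiseless
## RNFL / RGCLP thickness fields, and structural defects.
##
## Coordinate convention (single convention everywhere): retinal mm,
## fovea at the origin, x positive toward the optic disc for a right eye
## (OD), y positive superior. Left eyes (OS) are generated mirrored about
## the vertical axis and are mirrored back to OD coordinates before any
## cross-eye analysis. Circumpapillary angles use the TSNIT convention
## (0 = temporal, 90 = superior, 180 = nasal, 270 = inferior), which runs
## counter-clockwise for OD in screen coordinates.

wrap_angle <- function(d) ((d + 180) %% 360) - 180

# TSNIT angle <-> geometric angle (degrees, atan2 convention) conversions.
tsnit_to_geom <- function(theta, side = "OD") {
  if (side == "OD") (180 - theta) %% 360 else theta %% 360
}
geom_to_tsnit <- function(phi, side = "OD") {
  if (side == "OD") (180 - phi) %% 360 else phi %% 360
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Eye geometry: disc centre, fovea centre, axis angle, side
#'
#' @param disc_centre,fovea_centre Length-2 mm coordinates.
#' @param fd_angle Fovea-to-disc axis angle in degrees relative to
#'   horizontal, expressed in the OD (right-eye) convention regardless of
#'   side; typically around -7 degrees.
#' @param side `"OD"` (right) or `"OS"` (left).
#' @return An object of class `eye_geometry`.
#' @export
eye_geometry <- function(disc_centre, fovea_centre = c(0, 0), fd_angle = -7,
                         side = c("OD", "OS")) {
  side <- match.arg(side)
  stopifnot(length(disc_centre) == 2L, length(fovea_centre) == 2L,
            is.finite(fd_angle))
  structure(list(disc_centre = as.numeric(disc_centre),
                 fovea_centre = as.numeric(fovea_centre),
                 fd_angle = as.numeric(fd_angle), side = side),
            class = "eye_geometry")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf("<eye_geometry> %s: fovea (%.2f, %.2f), disc (%.2f, %.2f), axis %.1f deg\n",
              x$side, x$fovea_centre[1], x$fovea_centre[2],
              x$disc_centre[1], x$disc_centre[2], x$fd_angle))
  invisible(x)
}

#' Mirror a geometry into OD coordinates
#' @param geometry An [eye_geometry()].
#' @return The geometry with x coordinates negated and side flipped.
#' @export
mirror_geometry <- function(geometry) {
  eye_geometry(c(-geometry$disc_centre[1], geometry$disc_centre[2]),
               c(-geometry$fovea_centre[1], geometry$fovea_centre[2]),
               geometry$fd_angle,
               if (geometry$side == "OD") "OS" else "OD")
}

#' Sample an eye geometry
#'
#' Draws a plausible fovea/disc configuration: fovea at the origin and the
#' disc at distance ~4.5 mm along a fovea-to-disc axis of ~-7 +/- 3 degrees
#' (truncated so the distance stays in \[3.5, 5.5\] mm and the angle in
#' \[-15, 15\] degrees). OS eyes are mirrored about the vertical axis.
#'
#' @param side `"OD"` or `"OS"`.
#' @param params A [phantom_params()] (only the `geometry` block is used).
#' @param jitter If `FALSE`, returns the defaults exactly (distance 4.5 mm,
#'   angle -7 degrees) with no sampling.
#' @param seed Optional integer seed for reproducibility.
#' @return An [eye_geometry()].
#' @export
make_geometry <- function(side = c("OD", "OS"), params = phantom_params(),
                          jitter = TRUE, seed = NULL) {
  side <- match.arg(side)
  g <- params$geometry
  if (!is.null(seed)) set.seed(seed)
  if (jitter) {
    d <- rtrunc_norm(1, g$fd_dist, g$fd_dist_sd, 3.5, 5.5)
    a <- rtrunc_norm(1, g$fd_angle, g$fd_angle_sd, -15, 15)
  } else {
    d <- g$fd_dist; a <- g$fd_angle
  }
  disc <- d * c(cos(a * pi / 180), sin(a * pi / 180))
  if (side == "OS") disc[1] <- -disc[1]
  eye_geometry(disc, c(0, 0), a, side)
}

#' Phantom parameter set
#'
#' All tunable constants of the synthetic eye. Defaults are frozen study
#' conditions:
#' * RNFL circumpapillary profile: double Gaussian hump (peaks at TSNIT
#'   70 and 290 degrees, base 60 um, amplitudes 100 um, angular SD
#'   25 degrees) on a plateau inside the 1.725-mm measurement circle with
#'   exponential radial decay (scale 2 mm) outside, giving a healthy
#'   G_ONH of ~95 um.
#' * Macular RGCLP: elliptical perifoveal annulus (peak 100 um at radius
#'   1.2 mm, foveal floor 20 um) with a nasal decline toward the disc.
#' * Measurement noise: per-visit uniform offsets of SD
#'   `3.4 / (1.96 * sqrt(2))` um (RNFL) and `1.6 / (1.96 * sqrt(2))` um
#'   (RGCLP) — calibrated so fitted 2.5% test-retest limits average 3.4 um
#'   (G_ONH) and 1.6 um (G_mac) — plus iid per-pixel texture (SD 2 um).
#' * Artifacts off by default (`centring_sd = 0`, `seg_error$p = 0`);
#'   sweeps and configs switch them on explicitly.
#'
#' @param ... Named overrides of any top-level entry; list entries
#'   (`rnfl`, `macula`, `seg_error`, `geometry`) are merged element-wise.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(...) {
  p <- list(
    spacing_mm = 0.03,
    rnfl = list(base = 60, peak_amp = c(100, 100), peak_angle = c(70, 290),
                peak_width = 25, circle_radius = 1.725, radial_scale = 2),
    macula = list(floor = 20, peak = 100, peak_radius = 1.2,
                  sigma_in = 0.35, sigma_out = 1.0, ellip_y = 0.9,
                  asym_drop = 0.5, asym_x0 = 2.0, asym_scale = 0.5,
                  defect_rmin = 0.4, defect_rmax = 3.2, uniform = NULL),
    noise_sd = c(rnfl = 3.4 / (stats::qnorm(0.975) * sqrt(2)),
                 rgclp = 1.6 / (stats::qnorm(0.975) * sqrt(2))),
    pixel_noise_sd = 2,
    centring_sd = 0,
    seg_error = list(p = 0, depth = 20, width = 15,
                     vessel_angles = c(45, 110, 250, 315),
                     radial_halfwidth = 0.45, targets = "RNFL"),
    age_slope = -0.2, age_ref = 60,
    geometry = list(fd_dist = 4.5, fd_dist_sd = 0.3,
                    fd_angle = -7, fd_angle_sd = 3))
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(p)) stop("unknown phantom parameter: ", nm)
    if (is.list(p[[nm]]) && is.list(ov[[nm]])) {
      bad <- setdiff(names(ov[[nm]]), names(p[[nm]]))
      if (length(bad)) stop("unknown phantom parameter: ", nm, "$", bad[1])
      p[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else p[[nm]] <- ov[[nm]]
  }
  if (p$spacing_mm <= 0) stop("spacing_mm must be positive")
  if (any(p$noise_sd < 0) || p$pixel_noise_sd < 0 || p$centring_sd < 0)
    stop("noise and centring SDs must be >= 0")
  if (p$seg_error$p < 0 || p$seg_error$p > 1)
    stop("seg_error$p must be a probability in [0, 1]")
  class(p) <- "phantom_params"
  p
}

#' Wedge-shaped structural defect
#'
#' An arcuate bundle defect: an angular wedge (anchored at the disc centre
#' for the RNFL map, at the fovea for the macular map) inside which the
#' layer is thinned by `depth0 + rate * t` micrometres at follow-up time
#' `t` months. A width of 360 degrees turns the defect into diffuse
#' (global) thinning.
#'
#' @param angle_deg Angular position of the wedge centre, TSNIT degrees.
#' @param width_deg Full angular width in degrees.
#' @param depth0 Baseline depth in um (>= 0).
#' @param rate Progression rate in um/month (>= 0; 0 = static defect).
#' @param scope Which layer(s) the defect affects: `"RNFL"`, `"RGCLP"`
#'   or `"both"`.
#' @return An object of class `wedge_defect`.
#' @export
wedge_defect <- function(angle_deg, width_deg, depth0 = 0, rate = 0,
                         scope = c("RNFL", "RGCLP", "both")) {
  scope <- match.arg(scope)
  stopifnot(is.finite(angle_deg), width_deg > 0, width_deg <= 360,
            depth0 >= 0, rate >= 0)
  structure(list(angle_deg = angle_deg, width_deg = width_deg,
                 depth0 = depth0, rate = rate, scope = scope),
            class = "wedge_defect")
}

#' Diffuse (global) thinning
#'
#' Convenience wrapper: a 360-degree wedge affecting both layers.
#' @param rate Thinning rate in um/month.
#' @param depth0 Baseline diffuse loss in um.
#' @return A [wedge_defect()] of width 360 and scope `"both"`.
#' @export
diffuse_defect <- function(rate, depth0 = 0)
  wedge_defect(0, 360, depth0 = depth0, rate = rate, scope = "both")

defect_depth <- function(defect, t_months) defect$depth0 + defect$rate * t_months

# Apply all defects in scope to a field given polar coordinates about the
# anchoring centre. `theta` in TSNIT degrees, `r` in mm. A width-360 wedge
# ignores the radial band restriction. Wedge edges are anti-aliased by
# fractional pixel coverage (one pixel subtends ~ spacing/r radians of
# arc), so the circle-mean deficit matches depth x angular fraction to
# well under a percent despite the sharp-edged geometry.
apply_defects <- function(values, theta, r, defects, t_months, scope,
                          rband = NULL, spacing = NULL) {
  for (d in defects) {
    if (!(d$scope == scope || d$scope == "both")) next
    depth <- defect_depth(d, t_months)
    if (depth <= 0) next
    if (d$width_deg >= 360) {
      values <- values - depth
    } else {
      excess <- d$width_deg / 2 - abs(wrap_angle(theta - d$angle_deg))
      if (is.null(spacing)) {
        cov <- as.numeric(excess >= 0)
      } else {
        edge <- pmax(spacing / pmax(r, spacing), 1e-6) * 180 / pi
        cov <- pmin(pmax(excess / edge + 0.5, 0), 1)
      }
      if (!is.null(rband)) cov[r < rband[1] | r > rband[2]] <- 0
      values <- values - depth * cov
    }
  }
  values
}

# Grid of pixel-centre coordinates for a field of given origin/extent.
field_grid <- function(origin, extent, spacing) {
  nx <- round(extent[1] / spacing); ny <- round(extent[2] / spacing)
  xs <- origin[1] + (seq_len(nx) - 0.5) * spacing
  ys <- origin[2] + (seq_len(ny) - 0.5) * spacing
  list(x = matrix(xs, nx, ny), y = matrix(ys, nx, ny, byrow = TRUE),
       nx = nx, ny = ny)
}

#' Noiseless widefield RNFL thickness field
#'
#' Deterministic RNFL thickness over the 12 x 9 mm widefield patch: a
#' circumpapillary double-hump angular profile about the disc centre, flat
#' inside the 3.45-mm measurement circle and decaying exponentially with
#' radial distance outside it. Wedge defects subtract their current depth
#' inside their angular wedge; the result is floored at 0.
#'
#' @param geometry An [eye_geometry()].
#' @param params A [phantom_params()].
#' @param defects List of [wedge_defect()]s (scope RNFL or both apply).
#' @param t_months Follow-up time in months (>= 0), sets defect depths.
#' @param extent_mm,origin_mm Patch extent and lower-left corner; the
#'   default 12 x 9 mm patch spans x in \[-3.5, 8.5\] (OD) and y in
#'   \[-4.5, 4.5\] around the fovea.
#' @param spacing_mm Grid pitch, default from `params`.
#' @return A [thickness_map()] with layer `"RNFL"`.
#' @export
rnfl_field <- function(geometry, params = phantom_params(), defects = list(),
                       t_months = 0, extent_mm = c(12, 9), origin_mm = NULL,
                       spacing_mm = params$spacing_mm) {
  if (spacing_mm <= 0) stop("grid spacing must be positive")
  if (t_months < 0) stop("t_months must be >= 0")
  if (is.null(origin_mm)) {
    origin_mm <- if (geometry$side == "OD")
      geometry$fovea_centre + c(-3.5, -4.5)
    else geometry$fovea_centre + c(-8.5, -4.5)
  }
  g <- field_grid(origin_mm, extent_mm, spacing_mm)
  dx <- g$x - geometry$disc_centre[1]
  dy <- g$y - geometry$disc_centre[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- geom_to_tsnit(atan2(dy, dx) * 180 / pi, geometry$side)
  pr <- params$rnfl
  prof <- pr$base
  for (k in seq_along(pr$peak_amp))
    prof <- prof + pr$peak_amp[k] *
      exp(-wrap_angle(theta - pr$peak_angle[k])^2 / (2 * pr$peak_width^2))
  radial <- exp(-pmax(r - pr$circle_radius, 0) / pr$radial_scale)
  v <- prof * radial
  v <- apply_defects(v, theta, r, defects, t_months, "RNFL",
                     spacing = spacing_mm)
  thickness_map(pmax(v, 0), spacing_mm, origin_mm, "RNFL")
}

#' Noiseless macular RGCLP thickness field
#'
#' Deterministic ganglion cell layer plus inner plexiform layer thickness:
#' an elliptical perifoveal annulus ("donut") with a central foveal pit,
#' multiplied by a sigmoidal nasal decline toward the optic disc. Defects
#' are arcuate sectors of the annulus (angular wedge about the fovea,
#' radially restricted to the annulus band); a width-360 wedge is diffuse.
#'
#' @inheritParams rnfl_field
#' @param extent_mm Patch extent, default the 6 x 6 mm macular window.
#' @param origin_mm Lower-left corner; default centres the patch on the
#'   fovea. Pass the detected fovea minus half the extent to emulate an
#'   acquisition cropped about a mis-detected fovea.
#' @return A [thickness_map()] with layer `"RGCLP"`.
#' @export
rgclp_field <- function(geometry, params = phantom_params(), defects = list(),
                        t_months = 0, extent_mm = c(6, 6), origin_mm = NULL,
                        spacing_mm = params$spacing_mm) {
  if (spacing_mm <= 0) stop("grid spacing must be positive")
  if (t_months < 0) stop("t_months must be >= 0")
  if (is.null(origin_mm)) origin_mm <- geometry$fovea_centre - extent_mm / 2
  g <- field_grid(origin_mm, extent_mm, spacing_mm)
  m <- params$macula
  if (!is.null(m$uniform)) {
    v <- matrix(m$uniform, g$nx, g$ny)
    return(thickness_map(pmax(v, 0), spacing_mm, origin_mm, "RGCLP"))
  }
  dx <- g$x - geometry$fovea_centre[1]
  dy <- g$y - geometry$fovea_centre[2]
  re <- sqrt(dx^2 + (dy / m$ellip_y)^2)
  sig <- ifelse(re < m$peak_radius, m$sigma_in, m$sigma_out)
  v <- m$floor + (m$peak - m$floor) *
    exp(-(re - m$peak_radius)^2 / (2 * sig^2))
  # nasal decline toward the disc (x toward disc in OD convention)
  x_od <- if (geometry$side == "OD") dx else -dx
  v <- v * (1 - m$asym_drop * stats::plogis((x_od - m$asym_x0) / m$asym_scale))
  theta <- geom_to_tsnit(atan2(dy, dx) * 180 / pi, geometry$side)
  v <- apply_defects(v, theta, re, defects, t_months, "RGCLP",
                     rband = c(m$defect_rmin, m$defect_rmax),
                     spacing = spacing_mm)
  thickness_map(pmax(v, 0), spacing_mm, origin_mm, "RGCLP")
}
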