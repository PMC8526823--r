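#' Gridded retinal layer thickness map
#'
#' A `thickness_map` holds a 2-D grid of layer thicknesses (in micrometres)
#' over a rectangular patch of retina expressed in millimetre coordinates.
#' The grid follows the half-open cell convention: pixel `[i, j]` is centred
#' at `origin_mm + (c(i, j) - 0.5) * spacing_mm`, with the x index first
#' (increasing toward the optic disc for a right eye) and the y index second
#' (increasing superiorly). Values are non-negative; `NA` marks pixels with
#' no support (e.g. after rotation resampling).
#'
#' @param values Numeric matrix of thicknesses in micrometres, x index first.
#' @param spacing_mm Pixel pitch in mm (scalar, isotropic).
#' @param origin_mm Length-2 numeric, mm coordinates of the lower-left corner
#'   of the grid (the edge, not the first pixel centre).
#' @param layer Layer tag, `"RNFL"` or `"RGCLP"`.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(values, spacing_mm, origin_mm, layer = c("RNFL", "RGCLP")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  if (length(origin_mm) != 2L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be two finite numbers")
  if (any(values < 0, na.rm = TRUE))
    stop("thickness values must be >= 0")
  structure(
    list(values = values,
         spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm),
         extent_mm = dim(values) * spacing_mm,
         layer = layer),
    class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s, %d x %d px, %.2f x %.2f mm @ %.3f mm\n",
              x$layer, nrow(x$values), ncol(x$values),
              x$extent_mm[1], x$extent_mm[2], x$spacing_mm))
  v <- x$values[is.finite(x$values)]
  cat(sprintf("  thickness range %.1f - %.1f um (mean %.1f), %d missing px\n",
              min(v), max(v), mean(v), sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
plot.thickness_map <- function(x, ...,
                               main = sprintf("%s thickness (um)", x$layer)) {
  nx <- nrow(x$values); ny <- ncol(x$values)
  xs <- x$origin_mm[1] + (seq_len(nx) - 0.5) * x$spacing_mm
  ys <- x$origin_mm[2] + (seq_len(ny) - 0.5) * x$spacing_mm
  graphics::image(xs, ys, x$values, asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                  main = main, col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

# Pixel-centre coordinate vectors of a map grid.
map_axes <- function(map) {
  list(x = map$origin_mm[1] + (seq_len(nrow(map$values)) - 0.5) * map$spacing_mm,
       y = map$origin_mm[2] + (seq_len(ncol(map$values)) - 0.5) * map$spacing_mm)
}

#' Bilinear interpolation of a thickness map
#'
#' Samples the map at arbitrary mm coordinates by bilinear interpolation
#' between pixel centres. Points beyond the outer pixel centres but inside
#' the grid edge are clamped to the border value; points outside the grid
#' return `NA`.
#'
#' @param map A [thickness_map()].
#' @param x,y Numeric vectors of mm coordinates (recycled to common length).
#' @return Numeric vector of interpolated thicknesses (um).
#' @export
map_value <- function(map, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  sp <- map$spacing_mm
  nx <- nrow(map$values); ny <- ncol(map$values)
  # continuous pixel index (1 at first pixel centre)
  fx <- (x - map$origin_mm[1]) / sp + 0.5
  fy <- (y - map$origin_mm[2]) / sp + 0.5
  out <- rep(NA_real_, n)
  inside <- fx >= 0.5 & fx <= nx + 0.5 & fy >= 0.5 & fy <= ny + 0.5
  if (!any(inside)) return(out)
  fxc <- pmin(pmax(fx[inside], 1), nx)
  fyc <- pmin(pmax(fy[inside], 1), ny)
  i0 <- pmin(floor(fxc), nx - 1L); j0 <- pmin(floor(fyc), ny - 1L)
  i0 <- pmax(i0, 1L); j0 <- pmax(j0, 1L)
  tx <- fxc - i0; ty <- fyc - j0
  v <- map$values
  out[inside] <-
    v[cbind(i0,     j0)]     * (1 - tx) * (1 - ty) +
    v[cbind(i0 + 1, j0)]     * tx       * (1 - ty) +
    v[cbind(i0,     j0 + 1)] * (1 - tx) * ty +
    v[cbind(i0 + 1, j0 + 1)] * tx       * ty
  out
}

#' Mirror a map into right-eye (OD) coordinates
#'
#' Left-eye scans are mirrored about the vertical axis so that a single
#' coordinate convention (x positive toward the disc) is used everywhere.
#'
#' @param map A [thickness_map()].
#' @return The mirrored map.
#' @export
mirror_map <- function(map) {
  thickness_map(map$values[rev(seq_len(nrow(map$values))), , drop = FALSE],
                map$spacing_mm,
                c(-(map$origin_mm[1] + map$extent_mm[1]), map$origin_mm[2]),
                map$layer)
}

#' Write a thickness map as TIFF plus JSON sidecar
#'
#' The grid is stored as a single-channel 32-bit float TIFF. Because the
#' float TIFF writer stores values in \[0, 1\], thicknesses are scaled by
#' 1/1000 on disk; the scale is recorded in the sidecar
#' (`um_per_stored_unit`), alongside extent, origin, spacing, layer and any
#' extra metadata supplied.
#'
#' @param map A [thickness_map()].
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param meta Optional named list of extra sidecar fields
#'   (e.g. `eye_id`, `visit_months`).
#' @return `path`, invisibly.
#' @export
write_thickness_map <- function(map, path, meta = list()) {
  stopifnot(inherits(map, "thickness_map"))
  v <- map$values
  v[!is.finite(v)] <- 0
  # TIFF rasters are row-major from the top row: transpose and flip y
  tiff::writeTIFF(t(v[, rev(seq_len(ncol(v))), drop = FALSE]) / 1000,
                  path, bits.per.sample = 32L)
  sidecar <- c(list(extent_mm = map$extent_mm, origin_mm = map$origin_mm,
                    spacing_mm = map$spacing_mm, layer = map$layer,
                    um_per_stored_unit = 1000), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a thickness map written by [write_thickness_map()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return A [thickness_map()]; extra sidecar fields are attached as the
#'   `"meta"` attribute.
#' @export
read_thickness_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path) * side$um_per_stored_unit
  v <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  map <- thickness_map(v, side$spacing_mm, side$origin_mm, side$layer)
  known <- c("extent_mm", "origin_mm", "spacing_mm", "layer", "um_per_stored_unit")
  attr(map, "meta") <- side[setdiff(names(side), known)]
  map
}
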