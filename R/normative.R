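## Age-corrected normative model and per-pixel deviation / probability
## maps: per-pixel ordinary least squares of thickness on age over a
## normative cohort, with empirical residual quantiles at the 1% and 5%
## levels (one-sided: abnormal means thinner than expected).

#' Fit a per-pixel age-corrected normative model
#'
#' Ordinary least-squares regression of thickness on age at every pixel
#' of a congruent stack of normative maps, plus empirical type-1
#' quantiles (1st and 5th percentile) of the per-pixel residuals. Maps
#' must share grid, layer and orientation (mirror OS eyes and rotate to
#' the common axis first); `NA` pixels are ignored pixel-wise.
#'
#' @param maps List of [thickness_map()]s from healthy eyes (>= 20).
#' @param ages Numeric vector of ages (years), one per map.
#' @return An object of class `normative_model`: per-pixel `intercept`
#'   (um at `age_ref`), `slope` (um/year), residual quantiles `q01` and
#'   `q05`, grid metadata and `n_eyes`.
#' @export
fit_normative <- function(maps, ages) {
  if (length(maps) < 20)
    stop("at least 20 normative eyes are required to fit the model")
  if (length(ages) != length(maps))
    stop("`ages` must have one entry per map")
  ref <- maps[[1]]
  for (m in maps) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        abs(m$spacing_mm - ref$spacing_mm) > 1e-9 ||
        any(abs(m$origin_mm - ref$origin_mm) > ref$spacing_mm / 2) ||
        m$layer != ref$layer)
      stop("all normative maps must share grid and layer")
  }
  n <- length(maps)
  Y <- vapply(maps, function(m) as.vector(m$values), numeric(length(ref$values)))
  Y <- t(Y)                                   # eyes x pixels
  age_ref <- mean(ages)
  a <- ages - age_ref
  W <- is.finite(Y)
  Y0 <- ifelse(W, Y, 0)
  nj <- colSums(W)
  if (any(nj < 20)) stop("every pixel needs >= 20 non-missing normative eyes")
  Sa <- colSums(W * a); Saa <- colSums(W * a^2)
  Sy <- colSums(Y0); Say <- colSums(Y0 * a)
  denom <- nj * Saa - Sa^2
  slope <- ifelse(denom > 1e-12, (nj * Say - Sa * Sy) / denom, 0)
  intercept <- (Sy - slope * Sa) / nj
  res <- Y - matrix(intercept, n, ncol(Y), byrow = TRUE) -
    outer(a, slope)
  qs <- apply(res, 2, stats::quantile, probs = c(0.01, 0.05),
              type = 1, na.rm = TRUE, names = FALSE)
  dmn <- dim(ref$values)
  structure(list(
    intercept = matrix(intercept, dmn[1], dmn[2]),
    slope = matrix(slope, dmn[1], dmn[2]),
    q01 = matrix(qs[1, ], dmn[1], dmn[2]),
    q05 = matrix(qs[2, ], dmn[1], dmn[2]),
    age_ref = age_ref, n_eyes = n,
    spacing_mm = ref$spacing_mm, origin_mm = ref$origin_mm,
    layer = ref$layer),
    class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %s, %d x %d px, %d eyes (age ref %.1f y)\n",
              x$layer, nrow(x$intercept), ncol(x$intercept), x$n_eyes,
              x$age_ref))
  cat(sprintf("  median slope %.3f um/y; median q05 %.2f um\n",
              stats::median(x$slope, na.rm = TRUE),
              stats::median(x$q05, na.rm = TRUE)))
  invisible(x)
}

#' Age-corrected deviation / probability map
#'
#' Subtracts the age-predicted normative thickness from an observed map
#' and classes every pixel against the normative residual quantiles:
#' `p<1%` (deviation at or below the 1st percentile), `p<5%` (between the
#' 1st and 5th) or within normal limits.
#'
#' @param map A [thickness_map()] on the model's grid.
#' @param age The eye's age in years.
#' @param model A [fit_normative()] model.
#' @return An object of class `probability_map`: `deviation` (um matrix)
#'   and `class` (integer matrix with levels attribute
#'   `c("p<1%", "p<5%", "within-normal")`), plus grid metadata.
#' @export
deviation_map <- function(map, age, model) {
  stopifnot(inherits(map, "thickness_map"), inherits(model, "normative_model"))
  if (!identical(dim(map$values), dim(model$intercept)) ||
      abs(map$spacing_mm - model$spacing_mm) > 1e-9 ||
      any(abs(map$origin_mm - model$origin_mm) > model$spacing_mm / 2))
    stop("map grid does not match the normative model grid")
  dev <- map$values - (model$intercept + model$slope * (age - model$age_ref))
  cls <- matrix(3L, nrow(dev), ncol(dev))
  cls[dev <= model$q05] <- 2L
  cls[dev <= model$q01] <- 1L
  cls[!is.finite(dev)] <- NA_integer_
  attr(cls, "levels") <- c("p<1%", "p<5%", "within-normal")
  structure(list(deviation = dev, class = cls,
                 spacing_mm = map$spacing_mm, origin_mm = map$origin_mm,
                 layer = map$layer),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  tot <- sum(is.finite(x$deviation))
  cat(sprintf("<probability_map> %s, %d x %d px\n", x$layer,
              nrow(x$deviation), ncol(x$deviation)))
  cat(sprintf("  abnormal pixels: %.1f%% at p<5%%, %.1f%% at p<1%%\n",
              100 * sum(x$class <= 2L, na.rm = TRUE) / tot,
              100 * sum(x$class == 1L, na.rm = TRUE) / tot))
  invisible(x)
}

#' @export
plot.probability_map <- function(x, ...) {
  nx <- nrow(x$deviation); ny <- ncol(x$deviation)
  xs <- x$origin_mm[1] + (seq_len(nx) - 0.5) * x$spacing_mm
  ys <- x$origin_mm[2] + (seq_len(ny) - 0.5) * x$spacing_mm
  graphics::image(xs, ys, x$class, asp = 1, zlim = c(1, 3),
                  col = c("red", "yellow", "grey90"),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("%s probability map", x$layer), ...)
  invisible(x)
}

#' Fraction of abnormal pixels in a probability map
#'
#' @param pmap A [deviation_map()] result.
#' @param level `"p<5%"` (abnormal at 5%, includes 1%) or `"p<1%"`.
#' @return Fraction of finite pixels classed abnormal.
#' @export
abnormal_fraction <- function(pmap, level = c("p<5%", "p<1%")) {
  level <- match.arg(level)
  k <- if (level == "p<5%") 2L else 1L
  sum(pmap$class <= k, na.rm = TRUE) / sum(is.finite(pmap$deviation))
}
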