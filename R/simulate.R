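## One-visit acquisition simulator: composes the noiseless fields at the
## visit time, then applies the measurement model — metric-scale offset
## noise, per-pixel texture noise, disc/fovea centring jitter and optional
## localized segmentation dents. Every stochastic event is logged so a
## visit can be replayed exactly from its log.

#' Ground-truthed synthetic eye
#'
#' Bundles everything that defines one simulated eye: status, geometry,
#' structural defects, age and the 24-2 mean deviation carried as an
#' inclusion attribute.
#'
#' @param status One of `"healthy_stable"`, `"patient_stable"`,
#'   `"patient_progressing"`. Stable statuses must have zero progression
#'   (all defect rates 0).
#' @param geometry An [eye_geometry()].
#' @param defects List of [wedge_defect()]s.
#' @param age Age at baseline, years.
#' @param md_24_2 24-2 visual field mean deviation in dB; study eyes must
#'   satisfy the early-glaucoma inclusion rule `md_24_2 >= -6`.
#' @param eye_id Identifier string.
#' @return An object of class `eye_truth`. The field `true_rate` is the
#'   global-equivalent G_ONH thinning rate in um/month implied by the
#'   defects (depth rate times angular fraction, summed over RNFL-scope
#'   defects).
#' @export
eye_truth <- function(status = c("healthy_stable", "patient_stable",
                                 "patient_progressing"),
                      geometry, defects = list(), age = 60,
                      md_24_2 = 0, eye_id = "eye") {
  status <- match.arg(status)
  stopifnot(inherits(geometry, "eye_geometry"))
  rates <- vapply(defects, function(d)
    if (d$scope %in% c("RNFL", "both")) d$rate * d$width_deg / 360 else 0,
    numeric(1))
  true_rate <- if (length(rates)) sum(rates) else 0
  if (status != "patient_progressing" && true_rate > 0)
    stop("stable eyes must not carry progressing defects")
  structure(list(eye_id = eye_id, status = status, geometry = geometry,
                 defects = defects, age = age, md_24_2 = md_24_2,
                 true_rate = true_rate),
            class = "eye_truth")
}

# Noiseless, age-adjusted fields of an eye at time t (months).
# The cross-sectional age effect is applied at the baseline age only:
# within-eye ageing over a <= 42-month follow-up is negligible relative to
# test-retest noise and is deliberately excluded so that "stable" means
# exactly zero true change.
base_fields <- function(eye, params, t_months, rgclp_origin = NULL) {
  shift <- params$age_slope * (eye$age - params$age_ref)
  rn <- rnfl_field(eye$geometry, params, eye$defects, t_months)
  rg <- rgclp_field(eye$geometry, params, eye$defects, t_months,
                    origin_mm = rgclp_origin)
  rn$values <- pmax(rn$values + shift, 0)
  rg$values <- pmax(rg$values + shift, 0)
  list(rnfl = rn, rgclp = rg)
}

seg_dent_mask <- function(map, centre, angle_tsnit, width_deg, radial_band,
                          side) {
  ax <- map_axes(map)
  dx <- outer(ax$x - centre[1], rep(1, length(ax$y)))
  dy <- outer(rep(1, length(ax$x)), ax$y - centre[2])
  r <- sqrt(dx^2 + dy^2)
  theta <- geom_to_tsnit(atan2(dy, dx) * 180 / pi, side)
  abs(wrap_angle(theta - angle_tsnit)) <= width_deg / 2 &
    r >= radial_band[1] & r <= radial_band[2]
}

apply_visit_artifacts <- function(base, eye, params, art) {
  rn <- base$rnfl; rg <- base$rgclp
  rn$values <- rn$values + art$noise_offset[["rnfl"]]
  rg$values <- rg$values + art$noise_offset[["rgclp"]]
  if (params$pixel_noise_sd > 0) {
    set.seed(art$pixel_seed)
    rn$values <- rn$values +
      matrix(stats::rnorm(length(rn$values), 0, params$pixel_noise_sd),
             nrow(rn$values))
    rg$values <- rg$values +
      matrix(stats::rnorm(length(rg$values), 0, params$pixel_noise_sd),
             nrow(rg$values))
  }
  for (ev in art$seg_events) {
    if (ev$target == "RNFL") {
      m <- seg_dent_mask(rn, eye$geometry$disc_centre, ev$angle_deg,
                         ev$width_deg, ev$radial_band, eye$geometry$side)
      rn$values[m] <- rn$values[m] - ev$depth
    } else {
      m <- seg_dent_mask(rg, eye$geometry$fovea_centre, ev$angle_deg,
                         ev$width_deg, ev$radial_band, eye$geometry$side)
      rg$values[m] <- rg$values[m] - ev$depth
    }
  }
  rn$values <- pmax(rn$values, 0)
  rg$values <- pmax(rg$values, 0)
  list(rnfl = rn, rgclp = rg)
}

#' Simulate one acquisition visit
#'
#' Composes the eye's noiseless fields at `t_months`, then applies the
#' measurement model: (i) a per-visit uniform offset per layer (SD
#' `params$noise_sd`, the metric-scale test-retest noise) plus iid
#' per-pixel texture noise; (ii) detected geometry = true geometry +
#' independent bivariate Gaussian jitter (SD `params$centring_sd`) for
#' disc and fovea; (iii) with probability `params$seg_error$p`, a
#' localized segmentation dent at one of the fixed "vessel" angles. The
#' macular map is cropped about the *detected* fovea, as an instrument
#' centring its 6 x 6 mm window on its own fovea estimate would. All
#' applied events are logged in `artifacts_applied`; the visit is fully
#' reproducible from `seed` (and replayable from the log via
#' [replay_visit()]).
#'
#' @param eye An [eye_truth()].
#' @param params A [phantom_params()].
#' @param t_months Visit time in months from baseline.
#' @param seed Integer seed for this visit's random draws.
#' @param base Optional precomputed [base_fields] for this eye and time
#'   (internal optimisation; they are deterministic given eye/params/t).
#' @return An object of class `scan_record` with fields `eye_id`,
#'   `visit_months`, `rnfl_map`, `rgclp_map`, `geometry_true`,
#'   `geometry_detected`, `artifacts_applied`, `md_24_2`, `age`.
#' @export
simulate_visit <- function(eye, params = phantom_params(), t_months = 0,
                           seed = 1, base = NULL) {
  stopifnot(inherits(eye, "eye_truth"))
  set.seed(seed)
  art <- list(
    noise_offset = c(rnfl = stats::rnorm(1, 0, params$noise_sd[["rnfl"]]),
                     rgclp = stats::rnorm(1, 0, params$noise_sd[["rgclp"]])),
    centring = list(disc = stats::rnorm(2, 0, params$centring_sd),
                    fovea = stats::rnorm(2, 0, params$centring_sd)),
    seg_events = list(),
    pixel_seed = sample.int(.Machine$integer.max, 1))
  se <- params$seg_error
  if (se$p > 0 && stats::runif(1) < se$p) {
    target <- if (length(se$targets) > 1) sample(se$targets, 1) else se$targets
    angle <- se$vessel_angles[sample.int(length(se$vessel_angles), 1)]
    rb <- if (target == "RNFL")
      params$rnfl$circle_radius + c(-1, 1) * se$radial_halfwidth
    else c(params$macula$peak_radius - se$radial_halfwidth,
           params$macula$peak_radius + se$radial_halfwidth)
    art$seg_events <- list(list(target = target, angle_deg = angle,
                                width_deg = se$width, depth = se$depth,
                                radial_band = rb))
  }
  fovea_det <- eye$geometry$fovea_centre + art$centring$fovea
  disc_det <- eye$geometry$disc_centre + art$centring$disc
  if (is.null(base)) {
    base <- base_fields(eye, params, t_months, rgclp_origin = fovea_det - 3)
  } else if (any(art$centring$fovea != 0)) {
    # the macular crop is anchored on the detected fovea: with centring
    # jitter the cached crop is invalid and must be regenerated
    shift <- params$age_slope * (eye$age - params$age_ref)
    rg <- rgclp_field(eye$geometry, params, eye$defects, t_months,
                      origin_mm = fovea_det - 3)
    rg$values <- pmax(rg$values + shift, 0)
    base$rgclp <- rg
  }
  maps <- apply_visit_artifacts(base, eye, params, art)
  geometry_detected <- eye_geometry(disc_det, fovea_det,
                                    eye$geometry$fd_angle, eye$geometry$side)
  structure(list(eye_id = eye$eye_id, visit_months = t_months,
                 rnfl_map = maps$rnfl, rgclp_map = maps$rgclp,
                 geometry_true = eye$geometry,
                 geometry_detected = geometry_detected,
                 artifacts_applied = art,
                 md_24_2 = eye$md_24_2, age = eye$age),
            class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("<scan_record> %s @ %.1f months (%s, age %.0f, MD %.1f dB)\n",
              x$eye_id, x$visit_months, x$geometry_true$side, x$age,
              x$md_24_2))
  cat(sprintf("  artifacts: offsets (%.2f, %.2f) um, %d segmentation event(s)\n",
              x$artifacts_applied$noise_offset[["rnfl"]],
              x$artifacts_applied$noise_offset[["rgclp"]],
              length(x$artifacts_applied$seg_events)))
  invisible(x)
}

#' Replay a visit from its artifact log
#'
#' Reconstructs the maps of a simulated visit from the noiseless fields
#' plus the logged artifact record, without re-drawing any randomness.
#' `replay_visit(eye, params, record$visit_months, record$artifacts_applied)`
#' reproduces `record`'s maps exactly.
#'
#' @param eye The [eye_truth()] the record came from.
#' @param params The [phantom_params()] used.
#' @param t_months Visit time of the record.
#' @param artifacts The `artifacts_applied` log of a `scan_record`.
#' @return List with elements `rnfl` and `rgclp` ([thickness_map()]s).
#' @export
replay_visit <- function(eye, params, t_months, artifacts) {
  fovea_det <- eye$geometry$fovea_centre + artifacts$centring$fovea
  base <- base_fields(eye, params, t_months, rgclp_origin = fovea_det - 3)
  apply_visit_artifacts(base, eye, params, artifacts)
}
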