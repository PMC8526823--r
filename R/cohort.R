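## Cohort generation: short-term test-retest pairs (the threshold
## calibration set), longitudinal study eyes with ground-truth progression
## labels, and a normative (healthy, cross-sectional) set for the
## age-corrected deviation maps.

#' Cohort specification
#'
#' Counts per stratum and follow-up timing. The defaults mirror the
#' reference study design: a short-term group of 151 eyes (49 healthy
#' controls + 102 patients, two scans within 6 months, zero true change)
#' and a study group of 104 eyes (76 patients of whom 31 truly progress,
#' plus 28 healthy controls) followed for 12-42 months (mean ~24.9,
#' SD ~8.7).
#'
#' @param n_short_hc,n_short_pat Short-term test-retest eyes (HC, patients).
#' @param n_study_pat,n_study_hc Study eyes (patients, healthy controls).
#' @param n_study_prog Number of truly progressing study patients
#'   (0 <= n <= `n_study_pat`).
#' @param n_normative Healthy eyes for the normative model.
#' @param followup_mean,followup_sd,followup_range Study follow-up
#'   interval distribution (months; Gaussian truncated to the range).
#' @param short_dt_range Test-retest interval range (months, max 6).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_short_hc = 49, n_short_pat = 102,
                        n_study_pat = 76, n_study_hc = 28,
                        n_study_prog = 31, n_normative = 60,
                        followup_mean = 24.9, followup_sd = 8.7,
                        followup_range = c(12, 42),
                        short_dt_range = c(0.25, 6)) {
  counts <- c(n_short_hc, n_short_pat, n_study_pat, n_study_hc)
  if (any(counts < 1)) stop("stratum counts must be >= 1")
  if (n_study_prog < 0 || n_study_prog > n_study_pat)
    stop("n_study_prog must lie in [0, n_study_pat]")
  if (n_normative < 0) stop("n_normative must be >= 0")
  if (short_dt_range[2] > 6)
    stop("short-term test-retest interval must be <= 6 months")
  structure(list(n_short_hc = n_short_hc, n_short_pat = n_short_pat,
                 n_study_pat = n_study_pat, n_study_hc = n_study_hc,
                 n_study_prog = n_study_prog, n_normative = n_normative,
                 followup_mean = followup_mean, followup_sd = followup_sd,
                 followup_range = followup_range,
                 short_dt_range = short_dt_range),
            class = "cohort_spec")
}

# Static (non-progressing) glaucomatous damage for a patient eye: one or
# two arcuate wedges near the superior/inferior bundle peaks.
sample_patient_defects <- function(params) {
  k <- sample(1:2, 1)
  lapply(seq_len(k), function(i) {
    hub <- sample(params$rnfl$peak_angle, 1)
    wedge_defect(angle_deg = hub + stats::rnorm(1, 0, 15),
                 width_deg = stats::runif(1, 20, 40),
                 depth0 = stats::runif(1, 10, 35),
                 rate = 0,
                 scope = sample(c("RNFL", "both"), 1, prob = c(0.4, 0.6)))
  })
}

# Progressive damage: deepen a wedge over time, sometimes with an added
# diffuse component.
sample_progression <- function(params) {
  defs <- list(wedge_defect(
    angle_deg = sample(params$rnfl$peak_angle, 1) + stats::rnorm(1, 0, 15),
    width_deg = stats::runif(1, 20, 45),
    depth0 = stats::runif(1, 0, 10),
    rate = stats::runif(1, 0.1, 0.4),
    scope = sample(c("RNFL", "both"), 1, prob = c(0.3, 0.7))))
  if (stats::runif(1) < 0.3)
    defs <- c(defs, list(diffuse_defect(rate = stats::runif(1, 0.02, 0.08))))
  defs
}

sample_eye <- function(id, group, status, spec, params) {
  side <- sample(c("OD", "OS"), 1)
  geom <- make_geometry(side, params)
  healthy <- status == "healthy_stable"
  md <- if (healthy) rtrunc_norm(1, 0.5, 1, -6, 3)
        else rtrunc_norm(1, -2.5, 1.5, -6, 2)
  defects <- list()
  if (status == "patient_stable") defects <- sample_patient_defects(params)
  if (status == "patient_progressing")
    defects <- c(sample_patient_defects(params), sample_progression(params))
  visits <- switch(group,
    shortterm = c(0, stats::runif(1, spec$short_dt_range[1],
                                  spec$short_dt_range[2])),
    study = c(0, rtrunc_norm(1, spec$followup_mean, spec$followup_sd,
                             spec$followup_range[1], spec$followup_range[2])),
    normative = 0)
  eye <- eye_truth(status, geom, defects, age = stats::runif(1, 40, 80),
                   md_24_2 = md, eye_id = id)
  eye$group <- group
  eye$visit_months <- visits
  eye
}

#' Generate a full ground-truthed phantom cohort
#'
#' Draws every eye of the specified cohort: short-term test-retest pairs
#' (always zero true change), study eyes with ground-truth stable /
#' progressing labels, and a normative healthy set. Fully deterministic
#' given `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param params A [phantom_params()].
#' @return An object of class `oct_cohort`: list with `eyes` (list of
#'   [eye_truth()]s carrying `group` and `visit_months`), `spec`, `params`,
#'   `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1,
                            params = phantom_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  eyes <- list()
  add <- function(n, group, status, prefix) {
    new <- lapply(seq_len(n), function(i)
      sample_eye(sprintf("%s%03d", prefix, i), group, status, spec, params))
    eyes <<- c(eyes, new)
  }
  add(spec$n_short_hc, "shortterm", "healthy_stable", "STH")
  add(spec$n_short_pat, "shortterm", "patient_stable", "STP")
  if (spec$n_study_prog > 0)
    add(spec$n_study_prog, "study", "patient_progressing", "PRG")
  if (spec$n_study_pat - spec$n_study_prog > 0)
    add(spec$n_study_pat - spec$n_study_prog, "study", "patient_stable", "PST")
  add(spec$n_study_hc, "study", "healthy_stable", "HCS")
  if (spec$n_normative > 0)
    add(spec$n_normative, "normative", "healthy_stable", "NRM")
  # per-eye visit seed bases, all below 2^31
  base <- sample.int(2^20, 1)
  for (i in seq_along(eyes))
    eyes[[i]]$seed_base <- (base + 131L * i) %% .Machine$integer.max
  structure(list(eyes = eyes, spec = spec, params = params, seed = seed),
            class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  grp <- vapply(x$eyes, `[[`, character(1), "group")
  st <- vapply(x$eyes, `[[`, character(1), "status")
  cat(sprintf("<oct_cohort> %d eyes (seed %d)\n", length(x$eyes), x$seed))
  cat(sprintf("  short-term pairs: %d | study: %d (%d progressing) | normative: %d\n",
              sum(grp == "shortterm"), sum(grp == "study"),
              sum(grp == "study" & st == "patient_progressing"),
              sum(grp == "normative")))
  invisible(x)
}

#' Eyes of one cohort stratum
#' @param cohort An [generate_cohort()] result.
#' @param group `"shortterm"`, `"study"` or `"normative"`.
#' @return List of eyes.
#' @export
cohort_eyes <- function(cohort, group) {
  Filter(function(e) e$group == group, cohort$eyes)
}

#' Ground-truth reference labels of study eyes
#'
#' Maps simulator ground truth onto the reference-standard strata used in
#' the evaluation tables: progressing patients are `RS-P`, stable patients
#' `RS-NP`, healthy controls `HC`.
#'
#' @param eyes List of [eye_truth()]s (e.g. `cohort_eyes(cohort, "study")`).
#' @return Character vector of labels, named by eye id.
#' @export
truth_labels <- function(eyes) {
  lab <- vapply(eyes, function(e) switch(e$status,
    patient_progressing = "RS-P",
    patient_stable = "RS-NP",
    healthy_stable = "HC"), character(1))
  names(lab) <- vapply(eyes, `[[`, character(1), "eye_id")
  lab
}

#' Extract global metrics for every visit of a cohort stratum
#'
#' Runs the full acquisition + metric pipeline: each visit is simulated
#' (with its logged artifacts) and the two global metrics are read off the
#' maps at the *detected* geometry — G_ONH from the derived 3.45-mm circle
#' at the detected disc centre, G_mac from the 6 x 6 mm window at the
#' detected fovea. Noiseless base fields are cached across a stable eye's
#' visits (they are deterministic and time-invariant for zero-rate eyes).
#'
#' @param cohort An [generate_cohort()] result.
#' @param group Stratum to process.
#' @param n_samples Circle samples for the G_ONH profile.
#' @return Data frame: `eye_id`, `status`, `visit`, `visit_months`,
#'   `md_24_2`, `g_onh`, `g_mac`.
#' @export
cohort_metrics <- function(cohort, group = "shortterm", n_samples = 256) {
  eyes <- cohort_eyes(cohort, group)
  params <- cohort$params
  rows <- vector("list", sum(lengths(lapply(eyes, `[[`, "visit_months"))))
  k <- 0L
  for (eye in eyes) {
    stable <- eye$true_rate == 0 &&
      !any(vapply(eye$defects, function(d) d$rate > 0, logical(1)))
    base <- NULL
    for (v in seq_along(eye$visit_months)) {
      t <- eye$visit_months[v]
      if (is.null(base) || !stable)
        base <- base_fields(eye, params, t)
      rec <- simulate_visit(eye, params, t, seed = eye$seed_base + v,
                            base = base)
      prof <- derive_circle_profile(rec$rnfl_map,
                                    rec$geometry_detected$disc_centre,
                                    n_samples = n_samples,
                                    side = rec$geometry_true$side)
      k <- k + 1L
      rows[[k]] <- data.frame(
        eye_id = eye$eye_id, status = eye$status, visit = v,
        visit_months = t, md_24_2 = eye$md_24_2,
        g_onh = g_onh(prof),
        g_mac = g_mac(rec$rgclp_map, rec$geometry_detected$fovea_centre),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Reshape visit metrics into test-retest / baseline-followup pairs
#'
#' @param metrics A [cohort_metrics()] data frame (two visits per eye).
#' @param metric `"g_onh"` or `"g_mac"`.
#' @return Data frame with one row per eye: `eye_id`, `baseline`, `retest`,
#'   `dt_months`.
#' @export
metric_pairs <- function(metrics, metric = c("g_onh", "g_mac")) {
  metric <- match.arg(metric)
  b <- metrics[metrics$visit == 1, ]
  f <- metrics[metrics$visit == 2, ]
  f <- f[match(b$eye_id, f$eye_id), ]
  if (any(is.na(f$eye_id))) stop("every eye needs two visits")
  data.frame(eye_id = b$eye_id,
             baseline = b[[metric]], retest = f[[metric]],
             dt_months = f$visit_months - b$visit_months,
             stringsAsFactors = FALSE)
}
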