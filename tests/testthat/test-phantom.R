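# Phantom geometry and noiseless thickness fields.

test_that("sampled geometry respects the anatomical conventions", {
  g_od <- make_geometry("OD", default_params, seed = 1)
  g_os <- make_geometry("OS", default_params, seed = 1)
  expect_gt(g_od$disc_centre[1], 0)   # disc is nasal: +x for a right eye
  expect_lt(g_os$disc_centre[1], 0)   # mirrored for a left eye
  expect_error(make_geometry("XX"), "arg")

  # jitter disabled: the exact canonical configuration
  g0 <- make_geometry("OD", default_params, jitter = FALSE)
  expect_equal(sqrt(sum((g0$disc_centre - g0$fovea_centre)^2)), 4.5)
  expect_equal(g0$fd_angle, -7)

  for (s in 1:25) {
    g <- make_geometry(sample(c("OD", "OS"), 1), default_params, seed = s)
    d <- sqrt(sum((g$disc_centre - g$fovea_centre)^2))
    expect_true(d >= 3.5 && d <= 5.5)
    expect_true(g$fd_angle >= -15 && g$fd_angle <= 15)
  }
})

test_that("the circumpapillary profile is a double hump with peaks at the bundles", {
  prof <- derive_circle_profile(rnfl0, canonical_eye$disc_centre, side = "OD")
  th <- prof$thickness
  n <- length(th)
  # prominent local maxima only: interpolation ripple in the inter-hump
  # troughs stays far below the bundle peaks
  is_peak <- th > th[c(n, 1:(n - 1))] & th > th[c(2:n, 1)] &
    th > min(th) + (max(th) - min(th)) / 2
  expect_identical(sum(is_peak), 2L)
  peaks <- sort(prof$angle_deg[is_peak])
  expect_equal(peaks, c(70, 290), tolerance = 0.03)
})

test_that("wedge defects thin the circle mean by depth x angular fraction", {
  cases <- list(c(depth = 30, width = 36), c(depth = 25, width = 20),
                c(depth = 12, width = 60))
  base <- g_onh_of(rnfl0, n_samples = 4096)
  for (cs in cases) {
    m <- rnfl_field(canonical_eye, default_params,
                    list(wedge_defect(70, cs["width"], depth0 = cs["depth"])))
    drop <- base - g_onh_of(m, n_samples = 4096)
    expect_equal(drop, unname(cs["depth"] * cs["width"] / 360),
                 tolerance = 0.01)
  }
})

test_that("defects progress linearly in time and stable fields are time-invariant", {
  stable <- rnfl_field(canonical_eye, default_params,
                       list(wedge_defect(70, 30, depth0 = 20, rate = 0)),
                       t_months = 24)
  expect_identical(stable$values,
                   rnfl_field(canonical_eye, default_params,
                              list(wedge_defect(70, 30, depth0 = 20)),
                              t_months = 0)$values)
  prog <- list(wedge_defect(70, 30, depth0 = 10, rate = 0.5))
  d0 <- g_onh_of(rnfl_field(canonical_eye, default_params, prog, 0),
                 n_samples = 1024)
  d24 <- g_onh_of(rnfl_field(canonical_eye, default_params, prog, 24),
                  n_samples = 1024)
  expect_equal(d0 - d24, 0.5 * 24 * 30 / 360, tolerance = 0.01)
})

test_that("the macular field has a foveal pit and an elliptical annulus", {
  pit <- map_value(rgclp0, 0, 0)
  peak <- map_value(rgclp0, 0, default_params$macula$peak_radius *
                      default_params$macula$ellip_y)
  expect_lt(pit, peak)
  expect_true(all(rgclp0$values >= 0))
  expect_equal(rgclp0$extent_mm, c(6, 6))
  expect_equal(rnfl0$extent_mm, c(12, 9))
})

test_that("uniform-override macular mode gives a constant field", {
  p <- phantom_params(macula = list(uniform = 73))
  m <- rgclp_field(canonical_eye, p)
  expect_true(all(m$values == 73))
  expect_equal(g_mac(m, canonical_eye$fovea_centre), 73)
})

test_that("a macular defect lowers the window mean by depth x pixel fraction", {
  def <- list(wedge_defect(70, 45, depth0 = 15, scope = "RGCLP"))
  md <- rgclp_field(canonical_eye, default_params, def)
  # brute-force pixel count: coverage = mean removed / depth
  frac <- mean((rgclp0$values - md$values)) / 15
  expect_gt(frac, 0.01)
  drop <- g_mac(rgclp0, c(0, 0)) - g_mac(md, c(0, 0))
  expect_equal(drop, 15 * frac, tolerance = 1e-9)
})

test_that("thickness is floored at zero under extreme defects", {
  m <- rnfl_field(canonical_eye, default_params,
                  list(wedge_defect(70, 60, depth0 = 500)))
  expect_true(all(m$values >= 0))
  expect_true(any(m$values == 0))
})

test_that("invalid parameters are rejected", {
  expect_error(rnfl_field(canonical_eye, default_params, spacing_mm = 0),
               "spacing")
  expect_error(rgclp_field(canonical_eye, default_params, spacing_mm = -1),
               "spacing")
  expect_error(phantom_params(noise_sd = c(rnfl = -1, rgclp = 1)), ">= 0")
  expect_error(phantom_params(seg_error = list(p = 1.5)), "probability")
  expect_error(wedge_defect(0, 30, depth0 = -5))
})
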