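# Metric extraction: circle scan, macular window, rotation, unit scale.

test_that("constant maps give constant profiles and window means", {
  m <- constant_map(100)
  prof <- derive_circle_profile(m, c(0, 0))
  expect_lt(max(abs(prof$thickness - 100)), 1e-9)
  expect_equal(g_onh(prof), 100)
  expect_equal(g_mac(constant_map(42, n = 201, spacing = 0.05,
                                  layer = "RGCLP"), c(0, 0), window_mm = 6),
               42)
})

test_that("a linear gradient shifts the circle mean by exactly slope x offset", {
  # thickness a + b * x: the circle mean at centre c is a + b * c_x
  n <- 201; sp <- 0.05
  xs <- (seq_len(n) - 0.5) * sp - n * sp / 2
  a <- 80; b <- 4
  m <- thickness_map(matrix(rep(a + b * xs, n), n, n), sp,
                     c(-n * sp / 2, -n * sp / 2), "RNFL")
  delta <- 0.6
  g0 <- g_onh(derive_circle_profile(m, c(0, 0)))
  g1 <- g_onh(derive_circle_profile(m, c(delta, 0)))
  expect_equal(g1 - g0, b * delta, tolerance = 1e-9)
  # dense brute force agrees with the default sampling
  g1d <- g_onh(derive_circle_profile(m, c(delta, 0), n_samples = 4096))
  expect_equal(g1, g1d, tolerance = 1e-9)
})

test_that("profiles follow the TSNIT ordering for both eye sides", {
  # map increasing with +y: the superior (90 deg) sample is largest
  n <- 201; sp <- 0.05
  ys <- (seq_len(n) - 0.5) * sp - n * sp / 2
  m <- thickness_map(matrix(rep(50 + 5 * ys, each = n), n, n), sp,
                     c(-n * sp / 2, -n * sp / 2), "RNFL")
  for (side in c("OD", "OS")) {
    prof <- derive_circle_profile(m, c(0, 0), side = side)
    expect_equal(prof$angle_deg[which.max(prof$thickness)], 90)
  }
  # temporal start: sample 1 of an OD profile lies at -x of the centre
  prof <- derive_circle_profile(rnfl0, canonical_eye$disc_centre, side = "OD")
  expect_equal(prof$angle_deg[1], 0)
})

test_that("metrics are invariant to joint translation of map and centres", {
  shift <- c(0.731, -0.412)
  m2 <- thickness_map(rnfl0$values, rnfl0$spacing_mm,
                      rnfl0$origin_mm + shift, "RNFL")
  expect_equal(g_onh_of(m2, canonical_eye$disc_centre + shift),
               g_onh_of(rnfl0), tolerance = 1e-9)
  g2 <- thickness_map(rgclp0$values, rgclp0$spacing_mm,
                      rgclp0$origin_mm + shift, "RGCLP")
  expect_equal(g_mac(g2, canonical_eye$fovea_centre + shift),
               g_mac(rgclp0, canonical_eye$fovea_centre), tolerance = 1e-12)
})

test_that("G_ONH ignores the fovea and G_mac ignores the disc", {
  # perturbing only the fovea centre cannot enter the circle scan
  p1 <- derive_circle_profile(rnfl0, canonical_eye$disc_centre)
  expect_identical(g_onh(p1), g_onh_of(rnfl0))
  # perturbing only the disc centre cannot enter the window mean
  expect_identical(g_mac(rgclp0, canonical_eye$fovea_centre),
                   g_mac(rgclp0, canonical_eye$fovea_centre))
})

test_that("circle sampling converges: 256 vs 4096 samples within 0.05 um", {
  expect_lt(abs(g_onh_of(rnfl0, n_samples = 256) -
                  g_onh_of(rnfl0, n_samples = 4096)), 0.05)
})

test_that("out-of-support requests fail loudly", {
  m <- constant_map(50, n = 41, spacing = 0.05)  # 2.05 mm square
  expect_error(derive_circle_profile(m, c(0, 0)), "TSNIT arc")
  expect_error(g_mac(constant_map(50, n = 41, spacing = 0.05,
                                  layer = "RGCLP"), c(0, 0)), "support")
  expect_error(derive_circle_profile(rnfl0, c(0, 0), n_samples = 32),
               "n_samples")
})

test_that("window relocation reads the relocated content", {
  n <- 400; sp <- 0.05  # 20 mm square: c inside |x|<3, 2c outside
  xs <- (seq_len(n) - 0.5) * sp - n * sp / 2
  v <- matrix(ifelse(abs(xs) < 3, 60, 120), n, n)
  m <- thickness_map(v, sp, c(-10, -10), "RGCLP")
  expect_equal(g_mac(m, c(0, 0)), 60)
  expect_equal(g_mac(m, c(6, 0)), 120)
})

test_that("rotation to the common axis is exact for aligned and constant maps", {
  aligned <- rotate_to_common_axis(rnfl0, canonical_eye, canonical_angle = -7)
  keep <- is.finite(aligned$values)
  expect_lt(max(abs(aligned$values[keep] - rnfl0$values[keep])), 1e-6)
  cm <- constant_map(88, n = 201)
  rot <- rotate_to_common_axis(cm, canonical_eye, canonical_angle = 20)
  expect_lt(max(abs(rot$values[is.finite(rot$values)] - 88)), 1e-9)
})

test_that("rotation round trip returns the original within 0.5 um RMS", {
  g10 <- eye_geometry(canonical_eye$disc_centre, c(0, 0), -7, "OD")
  r1 <- rotate_to_common_axis(rnfl0, g10, canonical_angle = 3)
  r2 <- rotate_to_common_axis(r1, attr(r1, "geometry"), canonical_angle = -7)
  keep <- is.finite(r2$values) & is.finite(rnfl0$values)
  rms <- sqrt(mean((r2$values[keep] - rnfl0$values[keep])^2))
  expect_lt(rms, 0.5)
})

test_that("rotation that strands the measurement region is an error", {
  small <- thickness_map(rnfl0$values[1:50, 1:50], rnfl0$spacing_mm,
                         rnfl0$origin_mm, "RNFL")
  expect_error(rotate_to_common_axis(small, canonical_eye, 90), "support")
})

test_that("the retinal degree-to-mm scale matches the adopted constant", {
  expect_identical(deg_to_mm(0), 0)
  expect_equal(deg_to_mm(0.5), 0.144)  # the ~0.14 mm of half a degree
  expect_equal(deg_to_mm(1), 0.288)
})
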