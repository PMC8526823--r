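# Shared fixtures: the canonical (jitter-free) right eye and its default
# noiseless fields, built once per test run.

default_params <- phantom_params()
canonical_eye <- make_geometry("OD", default_params, jitter = FALSE)
rnfl0 <- rnfl_field(canonical_eye, default_params)
rgclp0 <- rgclp_field(canonical_eye, default_params)

g_onh_of <- function(map, centre = canonical_eye$disc_centre,
                     n_samples = 256, side = "OD")
  g_onh(derive_circle_profile(map, centre, n_samples = n_samples, side = side))

constant_map <- function(value, n = 101, spacing = 0.05,
                         origin = c(-n * spacing / 2, -n * spacing / 2),
                         layer = "RNFL")
  thickness_map(matrix(value, n, n), spacing, origin, layer)

# small healthy phantom cohort on a coarse macular grid, for normative fits
normative_stack <- function(n, seed, spacing = 0.1, noise_sd = 2,
                            age_slope = -0.2, ages = NULL) {
  set.seed(seed)
  if (is.null(ages)) ages <- runif(n, 40, 80)
  p <- phantom_params(pixel_noise_sd = noise_sd, age_slope = age_slope)
  maps <- lapply(seq_len(n), function(i) {
    m <- rgclp_field(canonical_eye, p, spacing_mm = spacing)
    v <- m$values + p$age_slope * (ages[i] - p$age_ref)
    if (noise_sd > 0)
      v <- v + matrix(rnorm(length(v), 0, noise_sd), nrow(v))
    thickness_map(pmax(v, 0), m$spacing_mm, m$origin_mm, m$layer)
  })
  list(maps = maps, ages = ages, params = p)
}
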