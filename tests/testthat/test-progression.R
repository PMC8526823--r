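# Event thresholds by quantile regression and the classification rules.

make_pairs <- function(n, sigma_delta, seed, base_mean = 95, base_sd = 10,
                       hetero = FALSE) {
  set.seed(seed)
  baseline <- rnorm(n, base_mean, base_sd)
  sd_i <- if (hetero) sigma_delta * baseline / base_mean else sigma_delta
  data.frame(baseline = baseline, retest = baseline + rnorm(n, 0, sd_i))
}

test_that("the fitted 2.5% limit matches the Gaussian closed form", {
  sigma <- 1.73
  pairs <- make_pairs(5000, sigma, seed = 1)
  fit <- fit_event_threshold(pairs, tau = 0.025)
  expect_equal(fit$mean_cutoff, qnorm(0.975) * sigma, tolerance = 0.05)
  # intercept-only and linear fits agree under homoscedastic noise
  fit0 <- fit_event_threshold(pairs, tau = 0.025, model = "intercept")
  expect_equal(fit$mean_cutoff, fit0$mean_cutoff, tolerance = 0.05)
  expect_identical(fit0$slope, 0)
})

test_that("noiseless pairs give a zero cutoff and no flags", {
  pairs <- data.frame(baseline = seq(80, 110, length.out = 50))
  pairs$retest <- pairs$baseline
  fit <- fit_event_threshold(pairs)
  expect_equal(fit$mean_cutoff, 0, tolerance = 1e-8)
  expect_false(any(classify_event(pairs$baseline, pairs$retest, fit)))
})

test_that("baseline-proportional noise bends the lower quantile line down", {
  pairs <- make_pairs(4000, 2, seed = 3, base_sd = 25, hetero = TRUE)
  fit <- fit_event_threshold(pairs)
  expect_lt(fit$slope, 0)
  # and the linear model achieves no worse check loss than intercept-only
  fit0 <- fit_event_threshold(pairs, model = "intercept")
  expect_lte(fit$loss, fit0$loss)
})

test_that("classification is one-sided with ties counting as progression", {
  pairs <- make_pairs(200, 1.5, seed = 5)
  fit <- fit_event_threshold(pairs, model = "intercept")
  b <- 95
  lim <- predict(fit, b)
  expect_false(classify_event(b, b, fit))            # no change
  expect_true(classify_event(b, b + lim, fit))       # exactly at the limit
  expect_true(classify_event(b, b + lim - 1, fit))   # beyond it
  expect_false(classify_event(b, b + 10, fit))       # thickening never flags
})

test_that("degenerate baselines fall back to the intercept-only model", {
  pairs <- data.frame(baseline = rep(95, 60),
                      retest = 95 + rnorm(60, 0, 1))
  fit <- fit_event_threshold(pairs, model = "linear")
  expect_identical(fit$model, "intercept")
})

test_that("input contracts are enforced", {
  expect_error(fit_event_threshold(make_pairs(10, 1, 1)), "at least 30")
  bad <- make_pairs(40, 1, 1); bad$retest[3] <- NA
  expect_error(fit_event_threshold(bad), "non-finite")
  expect_error(fit_event_threshold(make_pairs(40, 1, 1), tau = 0.7), "tau")
  expect_error(fit_event_threshold(data.frame(x = 1:40)), "columns")
})

test_that("decision rules follow their boolean algebra", {
  expect_true(apply_rule(TRUE, FALSE, "OR"))
  expect_false(apply_rule(TRUE, FALSE, "AND"))
  expect_false(apply_rule(FALSE, FALSE, "OR"))
  expect_identical(apply_rule(c(TRUE, FALSE), c(TRUE, TRUE), "AND"),
                   c(TRUE, FALSE))
  expect_error(apply_rule(TRUE, TRUE, "XOR"), "arg")
})

test_that("the 5-um rule is boundary-inclusive on loss only", {
  expect_true(fixed_rule(-5))
  expect_false(fixed_rule(-4.6))  # flagged at a ~3.1-um CI, not at 5 um
  expect_false(fixed_rule(6))
  expect_error(fixed_rule(NA))
})

test_that("rule monotonicity holds on classified cohorts: AND <= single <= OR", {
  set.seed(8)
  n <- 400
  metrics <- data.frame(
    eye_id = rep(sprintf("e%03d", 1:n), each = 2),
    visit = rep(1:2, n),
    visit_months = rep(c(0, 24), n),
    g_onh = 95 + rnorm(2 * n, 0, 2),
    g_mac = 51 + rnorm(2 * n, 0, 1))
  thr_o <- fit_event_threshold(make_pairs(500, 1.7, 21))
  thr_m <- fit_event_threshold(make_pairs(500, 0.8, 22, base_mean = 51))
  calls <- classify_cohort(metrics, thr_o, thr_m)
  expect_true(all(calls$flag_and <= calls$flag_onh))
  expect_true(all(calls$flag_and <= calls$flag_mac))
  expect_true(all(calls$flag_onh <= calls$flag_or))
  expect_true(all(calls$flag_mac <= calls$flag_or))
})

test_that("the event threshold behaves as a fitted model object", {
  pairs <- make_pairs(200, 1.5, seed = 6)
  fit <- fit_event_threshold(pairs, metric = "G_ONH")
  expect_named(coef(fit), c("intercept", "slope"))
  expect_length(predict(fit, c(90, 100)), 2L)
  expect_length(residuals(fit), 200L)
  expect_output(print(fit), "G_ONH")
  expect_output(summary(fit), "flag rate")
})
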