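## Event-based progression: test-retest limits via quantile regression on
## short-term pairs, and the classification rules built on them.

pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# Exact minimiser of sum(pinball(r - a)) over a: the type-1 tau-quantile
# (lower endpoint of the minimising interval), by the subgradient
# condition #(r < a) <= n*tau <= #(r <= a).
pinball_intercept <- function(r, tau) {
  sort(r)[max(1L, ceiling(length(r) * tau))]
}

# Quantile line of y on x by exact partial minimisation: for fixed slope
# the optimal intercept is the exact residual quantile, and the profiled
# check loss is convex piecewise-linear in the slope, minimised by
# golden-section search.
quantile_line <- function(x, y, tau) {
  prof <- function(b) pinball_loss(y - b * x - pinball_intercept(y - b * x, tau), tau)
  bmax <- 5 * (stats::sd(y) + 1e-12) / stats::sd(x)
  opt <- stats::optimize(prof, c(-bmax, bmax), tol = 1e-10 * max(1, bmax))
  b <- opt$minimum
  a <- pinball_intercept(y - b * x, tau)
  list(intercept = a, slope = b, loss = pinball_loss(y - a - b * x, tau))
}

#' Fit an event-based progression threshold
#'
#' Estimates the test-retest limit of a global metric from short-term
#' pairs (two scans close enough in time that true change is zero) by
#' quantile regression: the `tau` quantile (default 0.025, the lower
#' 95%-interval bound) of the signed change `retest - baseline` as a
#' linear function of the baseline value, fitted by exact minimisation of
#' the pinball (check) loss. When the baseline values are degenerate the
#' fit falls back to the intercept-only model (the plain sample
#' quantile). The summary cutoff (`mean_cutoff`) is the mean absolute
#' fitted quantile over the observed baselines — the scalar "95% CI"
#' quoted for a metric.
#'
#' @param pairs Data frame with numeric columns `baseline` and `retest`
#'   (one row per test-retest pair), e.g. from [metric_pairs()]. At least
#'   30 pairs are required.
#' @param tau Quantile level in (0, 0.5]; 0.025 gives the one-sided
#'   lower 95% limit on thinning.
#' @param model `"linear"` (quantile line in baseline, the default) or
#'   `"intercept"` (constant quantile).
#' @param metric Optional metric name stored in the object.
#' @return An object of class `event_threshold` with `print()`,
#'   `summary()`, `coef()`, `predict()`, `residuals()` and `plot()`
#'   methods. `predict(fit, baseline)` gives the fitted quantile of the
#'   signed change at a baseline value; `mean_cutoff` its average
#'   magnitude.
#' @export
fit_event_threshold <- function(pairs, tau = 0.025,
                                model = c("linear", "intercept"),
                                metric = NULL) {
  model <- match.arg(model)
  if (!all(c("baseline", "retest") %in% names(pairs)))
    stop("`pairs` needs columns `baseline` and `retest`")
  x <- as.numeric(pairs$baseline); y <- as.numeric(pairs$retest) - x
  if (length(x) < 30) stop("at least 30 test-retest pairs are required")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in test-retest pairs")
  if (tau <= 0 || tau > 0.5) stop("tau must be in (0, 0.5]")
  if (model == "linear" && stats::sd(x) < 1e-8) model <- "intercept"
  fit <- if (model == "linear") quantile_line(x, y, tau)
         else {
           a <- pinball_intercept(y, tau)
           list(intercept = a, slope = 0, loss = pinball_loss(y - a, tau))
         }
  structure(list(metric = metric %||% "metric", tau = tau, model = model,
                 intercept = fit$intercept, slope = fit$slope,
                 mean_cutoff = mean(abs(fit$intercept + fit$slope * x)),
                 loss = fit$loss, n = length(x),
                 baseline = x, delta = y),
            class = "event_threshold")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.event_threshold <- function(x, ...) {
  cat(sprintf("Event threshold for %s (tau = %g, %s model, n = %d pairs)\n",
              x$metric, x$tau, x$model, x$n))
  cat(sprintf("  quantile line: delta = %.3f %+.4f * baseline\n",
              x$intercept, x$slope))
  cat(sprintf("  mean cutoff (|95%% limit|): %.2f um\n", x$mean_cutoff))
  invisible(x)
}

#' @export
summary.event_threshold <- function(object, ...) {
  cat(sprintf("Quantile-regression test-retest limit (%s)\n", object$metric))
  print(object)
  cat(sprintf("  baseline range: %.1f - %.1f um; check loss %.3f\n",
              min(object$baseline), max(object$baseline), object$loss))
  cat(sprintf("  empirical flag rate on the fitted pairs: %.1f%%\n",
              100 * mean(object$delta <=
                           object$intercept + object$slope * object$baseline)))
  invisible(object)
}

#' @export
coef.event_threshold <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @param object An `event_threshold`.
#' @param baseline Baseline metric values at which to evaluate the fitted
#'   quantile of the signed change.
#' @rdname fit_event_threshold
#' @export
predict.event_threshold <- function(object, baseline = object$baseline, ...)
  object$intercept + object$slope * as.numeric(baseline)

#' @export
residuals.event_threshold <- function(object, ...)
  object$delta - predict(object, object$baseline)

#' @export
plot.event_threshold <- function(x, ...) {
  graphics::plot(x$baseline, x$delta, pch = 16, cex = 0.5,
                 col = "grey40", xlab = sprintf("baseline %s (um)", x$metric),
                 ylab = "retest - baseline (um)",
                 main = sprintf("Test-retest change, tau = %g limit", x$tau),
                 ...)
  o <- order(x$baseline)
  graphics::lines(x$baseline[o], predict(x, x$baseline[o]),
                  col = "firebrick", lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Classify an event (single metric)
#'
#' An eye progresses on a metric when the follow-up change reaches or
#' exceeds the fitted test-retest limit, i.e. when
#' `followup - baseline <= predict(threshold, baseline)` (thinning at or
#' beyond the limit; ties count as progression). A non-negative change
#' never flags, so a degenerate zero limit leaves stable eyes unflagged.
#'
#' @param baseline,followup Metric values in um (vectorised).
#' @param threshold An [fit_event_threshold()] result.
#' @return Logical vector of progression flags.
#' @export
classify_event <- function(baseline, followup, threshold) {
  stopifnot(inherits(threshold, "event_threshold"))
  d <- followup - baseline
  d <= predict(threshold, baseline) & d < 0
}

#' Combine single-metric flags under a decision rule
#'
#' @param flag_onh,flag_mac Logical vectors of single-metric flags.
#' @param rule `"ONH"`, `"MAC"`, `"OR"` or `"AND"`.
#' @return Logical vector.
#' @export
apply_rule <- function(flag_onh, flag_mac, rule = c("ONH", "MAC", "OR", "AND")) {
  rule <- match.arg(rule)
  switch(rule,
         ONH = flag_onh,
         MAC = flag_mac,
         OR = flag_onh | flag_mac,
         AND = flag_onh & flag_mac)
}

#' The fixed "rule of 5 um"
#'
#' The clinical heuristic that flags progression when global cRNFL has
#' thinned by at least `cutoff` micrometres (default 5), regardless of the
#' fitted test-retest limit.
#'
#' @param delta_onh Signed G_ONH change (followup - baseline), um.
#' @param cutoff Loss cutoff in um.
#' @return Logical vector: `TRUE` when `-delta_onh >= cutoff`.
#' @export
fixed_rule <- function(delta_onh, cutoff = 5) {
  stopifnot(all(is.finite(delta_onh)))
  -delta_onh >= cutoff
}

#' Apply all progression rules to a two-visit cohort
#'
#' @param metrics A [cohort_metrics()] data frame with two visits per eye.
#' @param thr_onh,thr_mac Fitted [fit_event_threshold()]s for G_ONH and
#'   G_mac.
#' @param fixed_cutoff Cutoff of the fixed G_ONH rule (um).
#' @return Data frame with one row per eye: deltas and the per-rule flags
#'   `flag_onh`, `flag_mac`, `flag_or`, `flag_and`, `flag_5um`.
#' @export
classify_cohort <- function(metrics, thr_onh, thr_mac, fixed_cutoff = 5) {
  po <- metric_pairs(metrics, "g_onh")
  pm <- metric_pairs(metrics, "g_mac")
  flag_onh <- classify_event(po$baseline, po$retest, thr_onh)
  flag_mac <- classify_event(pm$baseline, pm$retest, thr_mac)
  data.frame(eye_id = po$eye_id,
             delta_onh = po$retest - po$baseline,
             delta_mac = pm$retest - pm$baseline,
             flag_onh = flag_onh, flag_mac = flag_mac,
             flag_or = apply_rule(flag_onh, flag_mac, "OR"),
             flag_and = apply_rule(flag_onh, flag_mac, "AND"),
             flag_5um = fixed_rule(po$retest - po$baseline, fixed_cutoff),
             stringsAsFactors = FALSE)
}
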