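---
title: "Simulating event-based glaucoma progression with global OCT metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating event-based glaucoma progression with global OCT metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octprog)
```

## What this package models

Event-based progression detection declares glaucomatous change when a
global OCT metric drops, between two visits, by more than its
test–retest variability. Two metrics are in clinical use: the average
circumpapillary RNFL thickness on the derived 3.45-mm circle scan
(G_ONH) and the average macular RGCLP thickness over the 6 × 6 mm
fovea-centred window (G_mac). `octprog` rebuilds the entire measurement
chain on synthetic eyes with known ground truth, so that every failure
mode of the metrics — local damage, centring error, segmentation
error — can be injected, isolated and quantified.

The chain is: phantom thickness fields → simulated acquisition (noise,
centring jitter, segmentation dents) → metric extraction at the
*detected* geometry → quantile-regression event thresholds from
short-term pairs → rule-based classification → confusion tables against
ground truth.

## The phantom

**Coordinates.** Retinal millimetres, fovea at the origin, x toward the
optic disc for a right eye, y superior. Left eyes are generated
mirrored and mirrored back (`mirror_map()`, `mirror_geometry()`) before
any cross-eye analysis; circumpapillary angles use the TSNIT convention
(temporal–superior–nasal–inferior–temporal). Grid pitch is 0.03 mm
(400 × 300 px widefield, 200 × 200 px macular window), a compromise
between circle-interpolation accuracy and runtime; pixel centres sit at
half-pitch offsets with half-open cells.

**Geometry.** The disc centre lies 4.5 ± 0.3 mm from the fovea along a
fovea–disc axis of −7 ± 3° (both truncated: distance to [3.5, 5.5] mm,
angle to [−15, 15]°).

**RNFL field.** An angular double-hump profile around the disc —
base 60 µm plus two Gaussian humps of amplitude 100 µm and angular SD
25° at TSNIT 70° and 290° (the superior and inferior arcuate bundles) —
flat inside the measurement circle (radius 1.725 mm) and decaying
exponentially outside it (scale 2 mm). The hump amplitude was set so
the healthy circle mean is ~95 µm
(`60 + 2·100·25·sqrt(2π)/360 ≈ 94.8`), a typical healthy G_ONH.

**RGCLP field.** An elliptical perifoveal annulus: peak 100 µm at
radius 1.2 mm (vertical axis compressed by 0.9), foveal floor 20 µm,
inner/outer Gaussian flanks of SD 0.35 / 1.0 mm, multiplied by a
sigmoidal nasal decline toward the disc (50% drop, midpoint 2 mm nasal,
scale 0.5 mm) — ganglion cells thin out approaching the disc. The
floor is kept well above zero so that additive measurement noise never
clips inside the analysis window.

**Defects.** `wedge_defect(angle, width, depth0, rate, scope)` thins
the layer by `depth0 + rate·t` µm inside an angular wedge anchored at
the disc (RNFL) or fovea (macular annulus band). Wedge edges are
anti-aliased by fractional pixel coverage so the circle-mean deficit
matches the closed form `depth · width/360` to well under 1%. A
width-360 wedge is diffuse thinning (`diffuse_defect()`). Fields are
floored at 0 µm. Progressing phantom patients carry one deepening
wedge (rate 0.1–0.4 µm/month, width 20–45°), 30% with an added diffuse
component (0.02–0.08 µm/month); stable patients carry static wedges
only. The ground-truth global-equivalent rate of an eye is
`sum(rate·width/360)` over its RNFL-scope defects.

**Measurement noise.** The metrics are spatial means, so only the
spatially coherent component of repeatability reaches them. Noise is
therefore modelled as a per-visit uniform offset per layer — the
maximally smooth, maximally correlated field, mapping one-to-one onto
the metric scale — plus iid per-pixel texture (SD 2 µm) that feeds the
pixel-level normative quantiles but averages out of the metrics
(2/√40000 ≈ 0.01 µm for G_mac). The offset SDs are calibrated
analytically: for a target mean cutoff `c` at τ = 0.025,
`σ = c / (1.96·√2)`, giving 1.227 µm (RNFL, target 3.4 µm) and
0.577 µm (RGCLP, target 1.6 µm). This is a documented calibration to
the published average limits, not a free fit; the acceptance suite
verifies that the *fitted* cutoffs land in [3.2, 3.6] µm and
1.6 ± 0.3 µm when the full pipeline is run at n = 5000 pairs.

**Artifacts.** Centring error adds independent bivariate Gaussian
jitter (SD `centring_sd`) to the *detected* disc and fovea; the macular
map is cropped about the detected fovea, exactly as an instrument
centring its window on its own fovea estimate. Segmentation errors are
localized dents (default 20 µm deep, 15° wide, radial half-width
0.45 mm) at one of four fixed "vessel" angles (TSNIT 45°, 110°, 250°,
315°), drawn with probability `seg_error$p` per visit. Both are off by
default — the frozen study conditions attribute all short-term
variability to the calibrated noise, and the sweeps inject artifacts
explicitly so their effects are never confounded. Every applied event
is logged in `artifacts_applied`, and `replay_visit()` reproduces the
maps exactly from the log.

**Within-eye ageing** is deliberately excluded (the cross-sectional age
slope, −0.2 µm/year, applies at the baseline age only): over a ≤ 42
month follow-up it amounts to ~0.5 µm, and including it would make
"stable" eyes drift, blurring the ground truth that the type-I
analysis needs. Stable means exactly zero true change.

## Metric extraction

The derived circle profile samples the map by bilinear interpolation at
256 equally spaced TSNIT angles (bilinear, not bicubic, so the
linear-gradient closed form `ΔG = b·δ` holds exactly and tests can use
it as an oracle). Convergence: |G_ONH(256) − G_ONH(4096)| < 0.05 µm on
the default phantom (tested); sweeps that measure sharp-edged dents use
4096 samples. G_mac averages the pixels whose centres fall in the
half-open 6 × 6 mm square, foveal pit included — whether commercial
devices exclude a central zone is unstated, so we do not guess (the
choice is a documented constant, not a hidden one). Requests that leave
map support are hard errors naming the violating arc.

`rotate_to_common_axis()` registers scans to a common fovea–disc angle
(default −7°) by bilinear resampling about the fovea–disc midpoint;
pixels rotated out of support become `NA` and are excluded from means.
The cohort metric path omits this step because spatial means are
rotation- and translation-invariant (tested to 10⁻⁹); rotation matters
for pixelwise analyses, and the normative workflow applies it there.

## Event thresholds

`fit_event_threshold()` fits the τ-quantile (default 0.025) of the
signed change `Δ = retest − baseline` as a linear function of baseline
by exact pinball-loss minimisation: for a fixed slope the optimal
intercept is the exact type-1 sample quantile of the residuals (the
subgradient condition), and the profiled objective is convex piecewise
linear in the slope, minimised by golden-section search to ~10⁻¹⁰ —
deterministic and far below every stated tolerance. Degenerate
baseline spread falls back to the intercept-only fit. The scalar
summary `mean_cutoff` is the mean |fitted quantile| over the observed
baselines.

Design choices that were genuinely open:

* **Sidedness.** The clinical wording is a two-sided "95% CI", but the
  classification targets loss, so the default is the one-sided lower
  τ = 0.025 quantile on signed change; both τ and the model form are
  arguments.
* **Covariate.** The quantile line is linear in the baseline value,
  with the intercept-only variant selectable — the exact published
  covariate is not recoverable, so both are provided.
* **Ties.** A change exactly at the limit counts as progression
  ("equal or greater"); a non-negative change never flags, so the
  degenerate noiseless case (zero cutoff) leaves stable eyes unflagged.
* **Sample sizes.** At the study's own n = 151 the fitted cutoff has a
  sampling SD of ~0.4 µm (quantile asymptotics:
  `sqrt(τ(1−τ)/n)/φ(z₀.₀₂₅)·σ_Δ`), so calibration checks run at
  n = 5000 pairs where the SD is ~0.07 µm; the type-I check uses 2000
  independent stable eyes. These sizes are the package's verification
  conditions, stated here so the numbers in the test suite are
  interpretable.

## Evaluation

`confusion()`/`table1()` count FN among ground-truth progressors, FP
among stable patients and healthy controls, and accuracy over patients
only (controls reported separately, mirroring the published table
layout). Percentages are rounded half-up to one decimal.
`paper_fixture()` rebuilds the published per-eye flags from the printed
counts. Two published inconsistencies are preserved, not hidden: 15/31
is 48.39%, printed 48.3 in the source table but 48.4 here (half-up);
and the source table's AND-rule healthy-control cell (2 eyes)
contradicts both its own OR cell and the text, which fix the
both-flagged count at 1 — the fixture follows the text, so `table1()`
reproduces every published cell except that one (it prints 3.6% (1)).

## Mechanism sweeps

Sweeps run on noiseless phantoms so artifact effects are unconfounded.
`centring_sweep()` offsets one centre in uniformly random directions
and recomputes both metrics; the untouched metric is reported alongside
and is zero to machine precision — the disc centre only enters the
circle scan and the fovea only the window (mechanism selectivity is
structural, and asserted to 10⁻⁹ µm). `segmentation_sweep()` injects
one dent on the follow-up scan only; in the noiseless case
|ΔG_ONH| = depth·width/360 exactly. `fovea_threshold_crossing()`
bisects (tolerance 0.01 mm) for the smallest fovea decentring whose
maximum-over-direction |ΔG_mac| reaches a threshold.

One quantitative limitation deserves emphasis. For a pure window mean,
translating the 6 × 6 mm window by δ changes the mean only through the
entering and leaving edge strips — an exact boundary identity:
`ΔG = (δ/36)·∮ f (u·n) ds`. The sensitivity is therefore bounded by
the map's *edge* asymmetry, about |edge-mean difference|/6 per mm of
offset. On a smooth phantom with a plausible nasal decline this is a
few µm/mm, so the calibrated G_mac cutoff is crossed at a few tenths
of a millimetre (the acceptance script reports the computed value; the
test suite asserts a sub-millimetre crossing exists). Real macular
maps, whose fine structure (vessels, local defects,
segmentation-boundary effects) a smooth phantom deliberately omits, can
show larger sensitivity at smaller offsets. The pixel-level story is
different and much stronger: because the foveal pit slope is steep, a
0.1–0.3 mm decentring produces a growing *annular band* of p < 5%
pixels in the deviation map while barely moving the window mean — the
simulated counterpart of the ring artifact seen clinically, and a
neat illustration of why probability maps notice what global averages
cannot.

## Normative model

`fit_normative()` regresses thickness on age per pixel (OLS, closed
form, vectorised) over ≥ 20 healthy maps on a common grid and stores
empirical type-1 residual quantiles at 1% and 5%; `deviation_map()`
classes observed-minus-predicted one-sidedly against them. No spatial
smoothing is applied — pixelwise empirical quantiles are the simplest
faithful construction, and held-out specificity is verified at
5% ± 2 percentage points. The local-damage demonstration asserts the
headline mechanism: a wedge flagged at p < 1% over > 90% of its
footprint while |ΔG_ONH| stays below the calibrated event threshold.

## What passing tests do and do not show

The phantom emulates the geometry, spatial scales, longitudinal design
and artifact mechanisms of widefield OCT cohorts; it does not emulate
speckle, B-scan physics, real segmentation algorithms, vessel shadows,
or inter-eye anatomical diversity beyond the parameterised geometry.
Green tests therefore validate the *measurement-chain logic* — metric
definitions, threshold estimation, rule algebra, artifact propagation —
and the mechanistic claims that are structural (selectivity, angular
fractions, trade-offs). They do not certify the absolute µm magnitudes
of artifact effects on real eyes, which are map-dependent; phantom
magnitudes are reported as computed, never fitted to match published
per-eye values.
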