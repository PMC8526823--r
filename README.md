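# octprog

Event-based glaucoma progression detection with global OCT summary
metrics, rebuilt as a fully simulated, ground-truthed pipeline.

## The problem

Clinicians track early glaucoma with two global optical coherence
tomography (OCT) measures:

* **G_ONH** — the average circumpapillary retinal nerve fibre layer
  (cRNFL) thickness on a derived circle scan of diameter 3.45 mm centred
  on the optic disc, interpolated from a 12 × 9 mm widefield volume;
* **G_mac** — the average retinal ganglion cell layer plus inner
  plexiform layer (RGCLP) thickness over a 6 × 6 mm macular window
  centred on the fovea.

In the standard *event-based* analysis an eye is called a progressor
when the change between two visits,
`Δ = G(follow-up) − G(baseline)`, falls at or beyond a test–retest
limit. The limit is the τ = 0.025 quantile of Δ estimated by quantile
regression (pinball-loss minimisation of `Δ ~ baseline`) on short-term
pairs — two scans taken ≤ 6 months apart, close enough that true change
is assumed zero. Single-metric flags are combined into **OR**, **AND**
and the clinical fixed "rule of 5 µm" (flag when G_ONH loses ≥ 5 µm).

These global averages perform poorly, for three mechanistic reasons this
package quantifies:

1. **local damage** — a wedge defect of depth *d* µm and angular width
   *w* degrees changes G_ONH by only `d·w/360` µm, usually far below the
   event threshold, while pixel-level normative probability maps flag it
   at p < 1%;
2. **centring error** — decentring the disc by ~0.1 mm changes G_ONH by
   a low-µm amount comparable to the threshold (and cannot touch G_mac);
   decentring the fovea changes only G_mac;
3. **segmentation error** — a localized dent of depth *d* over *w*
   degrees of the circle shifts G_ONH by exactly `d·w/360` µm, e.g. a
   ~4 µm artifact exceeds a ~3.4 µm limit but hides below the 5 µm rule.

The package provides: a phantom generator for longitudinal RNFL/RGCLP
thickness-map cohorts with ground truth and injectable artifacts;
geometry-aware metric extraction (derived circle scan, macular window,
rotation to the common fovea–disc axis); the quantile-regression event
threshold as a classed model object; all classification rules;
confusion-table evaluation including a built-in fixture of the published
per-rule counts; age-corrected normative deviation maps; and the three
mechanism sweeps.

## Worked example

Evaluate the five decision rules on the built-in fixture that encodes
the published per-eye flag counts (31 progressing patients by the
reference standard, 45 stable patients, 28 healthy controls):

```r
library(octprog)
fx <- paper_fixture()
format_table1(table1(fx, fx$label))
#>                   ONH          MAC          OR           AND          FIXED5
#> FN (n = 31)       "48.4% (15)" "29.0% (9)"  "12.9% (4)"  "64.5% (20)" "67.7% (21)"
#> FP (n = 45)       "17.8% (8)"  "6.7% (3)"   "22.2% (10)" "2.2% (1)"   "8.9% (4)"
#> Accuracy (n = 76) "69.7% (23)" "84.2% (12)" "81.6% (14)" "72.4% (21)" "67.1% (25)"
#> FP (n = 28 HC)    "7.1% (2)"   "21.4% (6)"  "25.0% (7)"  "3.6% (1)"   "0.0% (0)"
```

Reading the table: G_ONH alone misses 48.4% of truly progressing eyes
and its accuracy over the 76 patient eyes is 69.7%; the OR rule cuts the
miss rate to 12.9% but falsely flags 25% of healthy controls; the 5 µm
rule eliminates healthy-control false positives at the cost of missing
two thirds of progressors. (15/31 is 48.39%, printed half-up as 48.4.)

Run the same analysis end to end on a synthetic cohort mirroring the
study design (151 short-term test–retest eyes for calibration, 104 study
eyes of which 31 truly progress, mostly by local wedge damage):

```r
study <- run_study(list(cohort = list(n_short_hc = 49, n_short_pat = 102,
                                      n_study_pat = 76, n_study_hc = 28,
                                      n_study_prog = 31, n_normative = 0)),
                   seed = 7)
study$thresholds$g_onh
#> Event threshold for G_ONH (tau = 0.025, linear model, n = 151 pairs)
#>   quantile line: delta = -0.897 -0.0216 * baseline
#>   mean cutoff (|95% limit|): 2.90 um
format_table1(study$table1)
#>                   ONH          MAC          OR           AND          FIXED5
#> FN (n = 31)       "71.0% (22)" "80.6% (25)" "58.1% (18)" "93.5% (29)" "96.8% (30)"
#> FP (n = 45)       "6.7% (3)"   "2.2% (1)"   "8.9% (4)"   "0.0% (0)"   "0.0% (0)"
#> Accuracy (n = 76) "67.1% (25)" "65.8% (26)" "71.1% (22)" "61.8% (29)" "60.5% (30)"
#> FP (n = 28 HC)    "3.6% (1)"   "0.0% (0)"   "3.6% (1)"   "0.0% (0)"   "0.0% (0)"
```

With 151 calibration pairs the fitted cutoff carries visible sampling
error (2.90 µm here; it converges to ~3.4 µm at large n — see the
vignette). The synthetic study reproduces the qualitative failure: most
ground-truth progressors carry local damage whose global-average
footprint is below the event threshold, so FN rates are high under every
rule, and tightening or loosening cutoffs only trades FN against FP.

The mechanism sweeps are one call each:

```r
centring_sweep(phantom_params(), "disc_offset", magnitudes = c(0, 0.1))
fovea_threshold_crossing(phantom_params(), threshold = 1.6)
segmentation_sweep(phantom_params(), dent_depths = 40, dent_widths = 36)
```

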