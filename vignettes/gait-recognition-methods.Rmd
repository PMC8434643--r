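---
title: "Methods: plantar-pressure gait recognition with gaitwrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plantar-pressure gait recognition with gaitwrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gaitwrf)
```

## The problem

A flexible hydrogel sensor array (FHSA) — 36 piezoresistive sensing units of
50 mm x 50 mm arranged as a 6x6 grid — records the pressure distribution
under a foot during stance. Gait disorders (for example in-toeing,
out-toeing or toe walking) shift where and when the foot loads the ground,
so the time-resolved pressure pattern carries enough information to classify
the walking style. `gaitwrf` implements the complete recognition chain:
sensor calibration, signal preprocessing, feature extraction, and a
weighted-vote random forest, together with a synthetic data generator that
makes the whole chain testable end to end.

## Sensor physics and calibration

The sensing units respond piezoresistively: the relative resistance change
under in-plane load is `pi_x * Fx + pi_y * Fy`
(`relative_resistance_change()`), and the point-load surface stress field
and the geometric design rule used to dimension the units are available as
`surface_stress()`, `geometric_resistance_change()` and
`strain_at_position()`. Two readings of the printed design formulas are
possible in places; the package adopts the literal `l/(w*t)` second term of
the design rule and the inverse-5/2-power form of the position-stress check
(the classical point-load decay, which keeps the stress finite as the
footprint grows). Both live in single functions so the alternative readings
can be swapped without touching anything else.

Calibration maps conductance `G` (mS, the reciprocal of the measured
resistance in kOhm) to pressure `p` (kg cm^-2) through a quadratic with
zero intercept:

```{r}
curve <- fit_calibration(fhsa_calibration())
curve
```

The zero intercept is a physical constraint — the unloaded baseline reads
zero conductance and zero pressure — so the fit is ordinary least squares
on the basis `(G^2, G)` without an intercept term. OLS attains the global
RSS minimum in this basis; the test suite confirms it against a dense grid
search. The packaged table spans 0–0.25 kg cm^-2, which we treat as the
sensor's calibrated span. The fitted coefficients on the packaged table are
(`r round(fit_calibration(fhsa_calibration())$a, 4)`,
`r round(fit_calibration(fhsa_calibration())$b, 4)`), and the inverse map
`conductance_from_pressure()` takes the unique non-negative quadratic root,
round-tripping to 1e-9 relative.

## The synthetic gait generator

No walking-trial recordings are distributed with the sensor, so the
generator stands in for the acquisition hardware. It is a first-class,
tested module, not a fixture. What it emulates:

* **Four gait patterns** — `normal`, `in_toeing`, `out_toeing`,
  `toe_walking` — each defined by three stance-phase weight maps (heel
  strike, midstance, push-off) on the 6x6 grid, normalized to sum to 1 per
  phase. The published pressure-distribution maps for the four gaits are
  images rather than numbers, so the templates are parameterized choices:
  in-/out-toeing shift the load line medially/laterally and trade heel
  against forefoot share; toe walking suppresses heel contact and flattens
  the double-bump force envelope. They were designed once, to be pairwise
  distinguishable, and are exposed as a registry (`gait_patterns()`) so
  other template sets can be substituted.
* **A stance envelope** — a half-sine with a configurable midstance dip
  (the characteristic double-bump vertical ground-reaction force), time
  warped per trial. Frames are scaled so the peak summed grid force equals
  the subject's static single-foot pressure exactly.
* **Trial variability** — multiplicative log-normal jitter (default log-sd
  0.06) on the template cells and the envelope time warp, a realistic
  magnitude for repeated walks by one subject.
* **A 30-volunteer cohort** (`generate_cohort()`): six 5-year age groups
  over 16–45 years, an even gender split, weights 43–84 kg from
  gender-specific normals, and static single-foot pressures near half the
  body weight with a small left-over-right bias. The cohort size comes
  from the proportion sample-size formula `n = z^2 p(1-p)/e^2`
  (`sample_size(1.645, 0.5, 0.15)` = `r sample_size(1.645, 0.5, 0.15)`).
* **Measurement noise** — the additive model `f(t) = a(t) + omega * b(t)`
  with standard Gaussian white `b(t)` (the distribution is a package
  choice; the denoising stage assumes broadband noise), clipped at zero
  pressure. `add_noise()` is literal: the perturbation's standard
  deviation equals `omega` in the series' own units. At the dataset level
  noise enters the acquisition electronics on the *normalized voltage*
  signal, whose full scale corresponds to the sensor's calibrated
  0.25 kg cm^-2 span; `generate_gait_dataset()` therefore adds per-cell
  noise of sd `omega * 0.25` kg cm^-2 (the span is the `noise_scale`
  parameter). The default intensity is `omega = 0.1`.
* **Scale** — 600 trials by default: 30 volunteers x 20 trials, balanced
  over the four gaits, alternating left/right foot.

What it does **not** emulate: biomechanically realistic gait dynamics,
subject-specific foot geometry, sensor drift, or shoe–ground interaction.
A classifier accuracy obtained on this generator therefore demonstrates
that the pipeline extracts and uses class structure of the designed kind;
it is not a claim about accuracy on real recordings (the original
walking-trial data were never deposited, so the published 91.9% headline
is not reproducible and is explicitly out of scope).

## Preprocessing

Signals are max-normalized, `(X - Xmin)/(Xmax - Xmin)`, with *trial-level*
bounds: one (min, max) pair per foot per trial, the maximum being the
trial's single-foot peak. Using a single pair per trial (rather than per
channel) preserves the relative loading of the anatomical regions — which
is exactly the discriminative signal — while removing the between-subject
force scale.

Denoising is wavelet thresholding: decompose, shrink the detail
coefficients, reconstruct from the untouched approximation coefficients
plus the shrunk details. The transform is implemented in the package
(Daubechies `haar`/`db2`/`db4` filter banks, symmetric boundary extension,
exact reconstruction; coefficients validated against an independent DWT
implementation and frozen into the tests). Defaults, all configurable and
all package choices since the published description is generic:

| parameter | default | why |
|---|---|---|
| wavelet | `db4` | smooth enough for low-frequency gait envelopes |
| depth | 3 levels | keeps the stance envelope in the approximation band at 100 Hz |
| threshold | universal, `sigma * sqrt(2 log n)` | standard; `sigma` from the MAD of the finest details |
| mode | soft | smaller artifacts than hard thresholding on short traces |

On the 512-sample two-tone test signal the stage raises SNR by roughly
9 dB averaged over noise intensities 0.1–0.4 (recomputed by
`scripts/acceptance.R`).

## Features

Each trial becomes a fixed-length descriptor: per aggregated channel, the
**signal amplitude** (peak-to-trough range), **skewness** (`m3/m2^1.5`)
and **kurtosis** (`m4/m2^2`, Pearson convention — the Gaussian reference
value is 3; the convention is recorded here because excess kurtosis is the
other common choice). The aggregation level is open in the published
description; the default sums the grid into four anatomical regions (toes
= row 1, forefoot = rows 2–3, midfoot = rows 4–5, heel = row 6), giving 12
features. With ~500 training trials, the 108-dimensional per-cell
alternative (available via `aggregation = "cell"`) invites overfitting.
Degenerate channels (zero variance) yield `NA` features rather than
errors, so an all-zero recording is flagged, not fatal.

## The weighted random forest

Tree induction is standard and is delegated to the `randomForest` package:
CART trees with Gini impurity, grown on with-replacement bootstrap
resamples with `floor(sqrt(d))` candidate features per split. The depth
cap is applied as a `2^max_depth` terminal-node limit (the underlying
implementation has no direct depth parameter). Defaults — 100 trees, depth
cap 10, minimum leaf size 2 — are package choices; the published tuning
reports which parameters were adjusted but not their values.

What is bespoke is the voting. Each tree `i` is scored by its
macro-averaged F-measure `F(i)` on its own out-of-bag rows (the rows its
bootstrap resample missed — an unbiased choice; training-set F would be
optimistic, and is used only as a warned fallback when the out-of-bag set
is empty), floored at 1e-6. The voting weight is

    W(i) = 1 - ((sum_j F(j)) / F(i) - n - 2) / n

This grouping of the published expression was adopted because it is the
reading that (a) increases with `F(i)` — better trees get more weight —
and (b) collapses to the uniform weight `1 + 2/n` when all trees score
equally, making weighted voting provably reduce to plain majority voting
in that case (a property the suite checks exactly, with a
summation-order-stable vote accumulation so ties break identically).
Weights are not renormalized — only relative magnitudes matter — and ties
break deterministically towards the lowest class index.

## Evaluation

Multi-class accuracy is the confusion-matrix trace over its total, which
reduces to `(TP+TN)/(TP+TN+FP+FN)` in the binary case; per-class
one-vs-rest TP/FP/FN/TN counts are also reported (the mean of per-class
binary accuracies equals trace/total only for balanced two-class problems,
which is why trace/total is the headline number). Per-volunteer accuracy
over that volunteer's test trials feeds the Pearson covariate analysis
against age, gender (female = 0, male = 1) and weight; a per-subject
outcome is required for that correlation to be defined.

`compare_pipelines()` is a controlled comparison: per seed, one forest is
trained and evaluated twice on identical test rows — once with the fitted
F-measure weights, once with uniform weights — so the arms differ *only*
in the voting. An optional SVM arm (radial kernel, `e1071`) trains on the
same split.

## Study conditions and observed behaviour

The benchmark mirrors the published experiment design: 600 trials, a
random 500/100 train/test split, four balanced classes. At the default
noise intensity 0.1 the pipeline reaches ~0.92–0.96 test accuracy across
seeds (well above the 4-class chance level 0.25). The weighted-vs-uniform
comparison runs at intensity 0.3, where trees are individually weak and
weighting has room to act; across seeds the weighted mean accuracy is
above the uniform mean, but the margin is small — on the order of 0.1
percentage point, within seed-to-seed noise for any single seed — which is
consistent with the modest (~1.3 percentage point) advantage the method
reports on real data. The suite asserts the ordering on a fixed 20-seed
panel; `scripts/acceptance.R` recomputes it for the seed it is given. On
this synthetic benchmark the SVM arm is competitive at high noise; the
published ordering of all three algorithms is a property of the original
recordings and is not asserted here.

Problem sizes used by the test suite were chosen to keep the full run in
the low minutes: module tests use 60–200 trial datasets and 15–50 trees;
the acceptance-level checks run the full 600-trial benchmark once plus the
20-seed comparison.

## Numerical choices and degenerate inputs

* Calibration inversion solves the quadratic in closed form; a degenerate
  curve (`a = b = 0`) and negative pressures are domain errors.
* The baseline calibration row (resistance 721.49 kOhm) is recorded with
  conductance zeroed, treated as the unloaded state, and excluded from
  reciprocal-consistency checks.
* The DWT requires `length >= 2^levels` and at least filter length minus
  one samples per level; shorter inputs error rather than silently pad.
* Vote accumulation uses order-stable row sums rather than BLAS products
  so that exact ties under equal weights are bitwise ties.
* All generators are deterministic given a seed; per-trial seeds derive
  from one master seed via a fixed integer stream, and every saved
  artifact records the seed and a stable configuration hash.

## Known limitations

* Synthetic data only: the generator defines the study conditions; results
  do not transfer to real recordings without recalibration.
* The Eq-style weight formula grouping, the wavelet family/depth/threshold,
  the feature aggregation level, and the forest hyperparameters are
  package choices where the published description is silent or ambiguous;
  each is documented above and isolated in code.
* Left and right feet are treated symmetrically by the same template set;
  foot-specific asymmetries beyond the static-pressure bias are not
  modelled.
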