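---
title: "Static and dynamic WM-GM functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic WM-GM functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgfc)
```

## The problem

Resting-state fMRI functional connectivity (FC) studies of Alzheimer's
disease have traditionally restricted themselves to gray matter (GM), treating
the white matter (WM) BOLD signal as noise. A growing body of work shows that
WM BOLD fluctuations carry neural information and correlate with specific GM
regions, which suggests that the *coupling between WM and GM* time series —
and in particular its temporal variability — may be a useful disease marker.

`wgfc` implements a complete, testable version of this analysis. From
per-subject ROI time series (82 GM parcels in a Brodmann-style atlas, 48 WM
parcels in a JHU-ICBM-style atlas, band-limited to 0.01–0.1 Hz) it builds
four feature families per subject:

* **sGFC** — static Pearson correlation between every GM ROI pair
  (3321 edges for 82 ROIs);
* **sWGFC** — static Pearson correlation between every WM–GM ROI pair
  (3936 edges for 48 × 82 ROIs);
* **dGFC**, **dWGFC** — their dynamic counterparts: the full series is cut
  into K overlapping windows (length 30 volumes, step 1; K = T − 29, so 111
  windows for T = 140) and each edge is summarised by the root mean square of
  its windowed correlations,
  \[
    \mathrm{RMS\text{-}dFC}_{ij} \;=\; \sqrt{\tfrac1K \sum_{k=1}^{K} (C_{ij}^{k})^{2}},
  \]
  a quadratic mean that measures the overall fluctuation level of the edge.

All values are Fisher r-to-z transformed (\(z = \operatorname{atanh} r\),
applied to RMS values too since they live in [0, 1]), edges are screened by
an edge-wise two-sample t-test at a p threshold, and the surviving feature
subset is benchmarked with a linear soft-margin SVM (cost C = 1, no feature
scaling) under leave-one-out (LOO) cross-validation, reporting accuracy,
sensitivity, specificity, F-score (percent) and AUC (fraction) with AD as
the positive class.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `windowLength`, `step` | 30, 1 volumes | sliding-window geometry; 30 volumes = 90 s at TR 3 s |
| `lowHz`, `highHz` | 0.01, 0.1 Hz | BOLD bandpass; `highHz` must stay below Nyquist 1/(2·TR) |
| `alphaStatic`, `alphaDynamic` | 0.001, 0.01 | selection thresholds (non-strict, p ≤ α) for static / dynamic features |
| `protocol` | `"nested"` | where selection runs relative to LOO folds (below) |
| `cost` | 1 | SVM cost C; the classifier is deliberately untuned |
| `fdrQ` | 0.05 | Benjamini–Hochberg level annotated in the top-edge report |
| `displayThreshold` | 0.5 | \|value\| cutoff for group-mean FC masks |

Window units are volumes (samples), not seconds: windows are defined on the
sampled series. The window must satisfy `windowLength ≤ T`; at
`windowLength = T` there is a single window and RMS-dFC reduces exactly to
\|static r\|, a property the test suite asserts.

## Selection protocols and leakage

The classical pipeline selects discriminative edges *once on the whole
cohort* and then cross-validates the classifier. That lets the held-out
subject influence feature choice and inflates accuracy on null data. Both
modes are provided and always recorded in the output metadata:

* `protocol = "paper"` — whole-cohort selection before LOO (the commonly
  practised, leakage-prone variant);
* `protocol = "nested"` (default) — the t-test and threshold are re-run
  inside every training fold, so the held-out subject never informs
  selection.

A dedicated test demonstrates that on pure-noise features the paper protocol
scores above the nested protocol on average. FDR correction is used only for
*reporting* the top edges; *selection* uses raw p thresholds.

## The synthetic cohort generator

Because the motivating clinical data are access-restricted, every stage is
validated against a generative model that produces exactly the structure the
analysis assumes — and nothing more. Each subject is a regime-switching
multivariate Gaussian: timepoints are drawn from a zero-mean Gaussian whose
correlation matrix is compound-symmetric at `baseCorrelation` (default 0.1,
a weak positive background typical of band-limited BOLD parcel data), and

* **static effects**: group B (AD) adds `staticEffectDelta` to the
  stationary correlation of chosen edges — detectable by static FC;
* **dynamic effects**: group B alternates between
  `baseCorrelation ± dynamicEffectDelta` (default amplitude 0.4) on chosen
  edges, with geometric regime dwell times of mean `stateDwell` (default 20
  samples = 60 s, in the range reported for connectivity state dwell times).
  The stationary mean is unchanged, so these edges are invisible to static
  FC but raise the RMS of windowed correlations — giving the dynamic
  statistic something only it can detect.

Defaults mirror the emulated study design: 45 subjects per group, 48 WM + 82
GM ROIs, TR 3 s. The study's per-subject series length is not recorded in
its public description; the default of 140 volumes (7 min at TR 3 s, a
typical resting-state duration) is a stand-in, not an asserted study value.
Generated series are bandpass-filtered with the *same* filter as the
extraction stage, so synthetic and extracted data enter the pipeline
identically.

Implied correlation matrices are eigenvalue-checked; a non-positive-
semidefinite configuration is rejected with an error naming the offending
edges, never silently projected — so injected test effects are exactly as
specified. One global seed derives per-subject streams by fixed offsets:
identical spec + seed is bit-identical, and subjects are independent.

`noiseSd` adds white measurement noise, which attenuates every observed
correlation by 1/(1 + noiseSd²). Its default is 0 so that injected
correlation deltas are recovered at face value (the calibration tests rely
on this); set it above 0 to study attenuation explicitly.

What the generator deliberately does **not** model: hemodynamic response
convolution, head motion, physiological noise, spatial autocorrelation
between parcels, and scanner drift. Passing tests therefore demonstrate
correctness of the *computations* under the model's assumptions, not
robustness of the scientific claim on real scanner data.

## Numerical choices

* **Bandpass**: zero-phase forward–backward Butterworth, order 2 per pass —
  standard rs-fMRI practice with no phase distortion of correlations. Columns
  are demeaned before filtering (a DC offset would otherwise excite edge
  transients, since no padding is used) and after. At TR 3 s the measured
  amplitude ratio is > 0.99 at 0.05 Hz and < 0.01 at 0.15 Hz.
* **Degenerate windows**: a zero-variance window makes Pearson r undefined;
  the windowed correlation is set to 0 and counted, keeping K identical
  across edges (dropping windows would desynchronise the RMS).
* **Fisher z clipping**: \|r\| is clipped to 1 − 10⁻⁷ before atanh so
  numerically perfect correlations stay finite; values outside [−1, 1]
  beyond 10⁻⁹ are an error, not a clip.
* **Edge order**: symmetric matrices vectorise as the strict upper triangle
  in row-major order; rectangular ones as the row-major W × G flatten. The
  order is fixed by the canonical (ascending-label) ROI order and guarded by
  an explicit check, so features align across subjects.
* **Ties**: top-edge ranking breaks p-value ties by \|t\| descending, then
  edge position — deterministic across runs. ROC thresholds sweep the unique
  pooled LOO decision scores; tied scores step the curve diagonally, making
  the trapezoidal AUC equal the tie-aware Mann–Whitney statistic.
* **Zero-variance ROIs** in static FC get 0 on their edges with a warning
  rather than NA propagation or silent removal.

## Open design points, resolved

* **Window data handling**: windowed correlations use standard Pearson per
  window, which demeans within the window implicitly.
* **Group-mean maps** (threshold 0.5, strict inequality on \|value\|) use
  raw r / RMS values; Fisher z is reserved for statistics.
* **AUC pooling**: LOO yields one decision score per subject; the ROC/AUC is
  computed from the pooled scores (per-fold ROC is undefined for single
  held-out points).
* **t-test family**: pooled-variance Student's t is the default (groups are
  equal-sized in the emulated design, where pooled and Welch coincide
  anyway); Welch is available via `variant = "welch"`.
* **Method comparisons on dynamic-only cohorts** (the generator's
  differentiating condition) are run at a common α = 0.01 for both static
  and dynamic feature sets: at α = 0.001 a truly-null static feature set is
  empty in some LOO fold with non-negligible probability, which by contract
  is an error; a common threshold makes the comparison about the
  connectivity statistic rather than the threshold.

## Problem sizes used in the shipped checks

The package's own validation runs at the emulated study scale — 45 + 45
subjects, 48 WM + 82 GM ROIs, 140 volumes — for the calibration,
chance-level and effect-recovery checks (5, 2 and 5 cohort replicates
respectively), and at reduced scale (≤ 30 subjects, ≤ 14 ROIs) for unit
tests of individual operations. The end-to-end evaluation script
(`scripts/acceptance.R`) uses one full-scale effect-bearing cohort and one
null cohort.

## Known limitations

* The regime-switching model gives the RMS statistic a clean target; real
  dynamic FC is not piecewise-stationary and window-length sensitivity is
  not explored (rectangular windows only, as in the emulated design).
* LOO accuracy on null data exhibits the well-known slight downward
  (anti-learning) bias; chance-level checks therefore use interval bands, not
  point equality.
* The classifier is intentionally untuned (linear kernel, C = 1); the
  package benchmarks *feature subsets*, not classifiers.
* With `noiseSd > 0`, injected deltas are recovered only up to the
  attenuation factor above; calibration examples assume the noise-free
  default.

## A minimal run

```{r example, eval = FALSE}
spec <- CohortSpec(nPerGroup = 10, nWm = 8, nGm = 12, nTimepoints = 140,
                   dynamicEffectEdges = crossEdges(1:3, 1:3, nWm = 8),
                   seed = 1)
cfg <- runConfig(mode = "simulate", spec = spec, seed = 1,
                 alphaStatic = 0.05, alphaDynamic = 0.05)
out <- runPipeline(cfg)
out$summary
```
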