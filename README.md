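# wgfc — static and dynamic WM–GM functional connectivity classification

`wgfc` is an R package for researchers studying whether the coupling between
white-matter (WM) and gray-matter (GM) BOLD signals discriminates Alzheimer's
disease (AD) patients from normal controls (NC). Conventional resting-state
fMRI connectomics stops at GM; this package implements the full
cross-compartment analysis: from band-limited (0.01–0.1 Hz) ROI time series
it builds four edge-feature families per subject —

- **sGFC** — static Pearson correlation within GM (82 ROIs → 3321 edges),
- **sWGFC** — static WM–GM correlation (48 × 82 ROIs → 3936 edges),
- **dGFC / dWGFC** — their dynamic counterparts, where the series is cut into
  K overlapping windows (length 30 volumes, step 1; K = T − 29) and each edge
  is summarised by the quadratic mean of its windowed correlations

  RMS-dFC<sub>ij</sub> = √( Σ<sub>k</sub> (C<sub>ij</sub><sup>k</sup>)² / K ),

then Fisher-z transforms all edges, screens them with an edge-wise two-sample
t-test at a p threshold (p ≤ 0.001 static / p ≤ 0.01 dynamic by default),
and benchmarks each feature subset with a linear SVM (C = 1) under
leave-one-out cross-validation, reporting ACC, SEN, SPE, F-score (per cent,
AD = positive class) and AUC.

Because the motivating clinical cohorts are access-restricted, the package
ships a regime-switching multivariate Gaussian cohort simulator that injects
group differences either in stationary correlation (a static-FC effect) or
in correlation *fluctuation* with the stationary mean unchanged (an effect
only the RMS statistic can see). Every pipeline stage is validated against
it. ROI extraction from NIfTI volumes with integer-label atlases is included
for image-based inputs.

## Worked example

Simulate a small two-group cohort where only the *fluctuation* of four WM–GM
edges differs between groups, then run the whole pipeline:

```r
library(wgfc)

spec <- CohortSpec(nPerGroup = 15, nWm = 10, nGm = 14, nTimepoints = 140,
                   dynamicEffectEdges = crossEdges(1:4, 1:4, nWm = 10),
                   seed = 42)
cfg <- runConfig(mode = "simulate", spec = spec, seed = 42,
                 alphaStatic = 0.05, alphaDynamic = 0.05)
out <- runPipeline(cfg)
out$summary
#>  method     acc     sen     spe  fscore    auc n_selected alpha
#>    sGFC 36.6667 40.0000 33.3333 38.7097 0.2178          7  0.05
#>   sWGFC  6.6667  6.6667  6.6667  6.6667 0.0044          6  0.05
#>    dGFC  0.0000  0.0000  0.0000      NA 0.0000          5  0.05
#>   dWGFC 70.0000 53.3333 86.6667 64.0000 0.8356          8  0.05
```

Only dWGFC — the dynamic WM–GM features — carries signal by construction,
and only it classifies above chance (70 % accuracy, AUC 0.84). The static
methods see nothing: their "selected" edges are noise, and leave-one-out
SVMs on noise show the familiar below-chance anti-learning scores. The
top-ranked edges recover the injected ones:

```r
head(out$topEdges, 3)
#>    row   col        t            p           q
#>  WM_04 GM_04 4.653539 7.148799e-05 0.006587115
#>  WM_03 GM_03 4.552782 9.410164e-05 0.006587115
#>  WM_01 GM_01 3.288566 2.718711e-03 0.097552327
```

`runPipeline()` writes per-method feature/edge-statistics/ROC tables,
group-mean FC masks (|value| > 0.5), the FDR-annotated top-edge table and a
reproducibility manifest under `cfg$outDir`. Individual stages are exported
too: `generateCohort()`, `extractRoiTimeseries()`, `bandpassFilter()`,
`staticFCWithin()`, `staticFCCross()`, `dynamicFC()`, `rmsFC()`,
`fisherZ()`, `edgeTTest()`, `selectEdges()`, `thresholdSweep()`,
`looSvm()`, `rocPoints()`. A command-line wrapper lives in
`inst/scripts/run-pipeline.R`.

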