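# speckleFlow

Quantitative laser speckle contrast imaging (LSCI) of tissue perfusion,
built for the surgical use case of telling ischemic from well-perfused
bowel before an anastomosis is made. The package provides a fully
testable reimplementation of the analysis chain around laparoscopic
LSCI: a physics-based speckle simulator with a closed-form oracle,
windowed contrast and perfusion mapping, ROI time series, Youden-index
cut-off estimation, a perfusion–lactate calibration, a study emulator,
and inter-observer agreement statistics.

## The quantities at the core

* **Speckle contrast** over a 7 × 7 pixel window:
  `K = σ/μ` (population SD over window mean). Moving red blood cells
  blur the speckle within the exposure `T`, so `K` falls as flow rises.
* **Time-integrated speckle physics** (simulator oracle), with
  `x = T/τc` the exposure-to-decorrelation ratio:
  `K²(x) = β (e^(−2x) − 1 + 2x) / (2x²)`, `K² → β` as `x → 0`.
* **Perfusion mapping**: `LSPU = min(1/K², cap)` (arbitrary units,
  cap 200 AU), so faster flow reads higher; a raw-contrast mode is kept
  for diagnostics.
* **Youden-optimal cut-off**: the threshold maximizing
  `J = sensitivity + specificity − 1`, scanned over midpoints between
  observed values; under the perfusion convention values strictly below
  the cut-off are classified ischemic.
* **Perfusion–lactate calibration**: ordinary least squares of lactate
  on `ln(LSPU)` with its coefficient of determination `R²`.
* **Inter-observer agreement**: signed along-midline placement
  distances (positive toward ischemic tissue), fractions within a
  distance band, and unweighted Cohen's kappa
  `κ = (p_o − p_e)/(1 − p_e)` with a seeded bootstrap CI.

## Worked example

Simulate a bowel-loop phantom (well-perfused target 95 AU, ischemic
50 AU), image it, and recover zone perfusion through the full mapping
chain:

```r
library(speckleFlow)

ph <- makeLoopPhantom(160, 400, exposure = 5,
                      zoneTargets = c(well = 95, ischemic = 50),
                      bandHeight = 80)
st <- generateSpeckleStack(ph, nFrames = 6, seed = 17)
maps <- lapply(seq_len(nFrames(st)), function(f)
  lspuMap(contrastMap(frames(st)[, , f], 7), cap = 200))
rs <- roiSeries(selectMiddleFrames(maps, 4), defaultLoopROIs(ph),
                loopId = "phantom", timepoint = "T0")
rs$summary[, c("roi_id", "zone", "n_frames", "mean", "sd")]
#>            roi_id            zone n_frames   mean     sd
#> 1            well            well        4 102.35 0.8273
#> 2  watershed_left  watershed_left        4  81.05 2.4926
#> 3        ischemic        ischemic        4  55.20 1.3084
#> 4 watershed_right watershed_right        4  77.47 1.9553
```

The 60 × 60 px ROI means recover the configured zone perfusion within
the pipeline's 15% tolerance (the residual upward shift is the known
small-window bias of the 1/K² index, discussed in the vignette), and
the watershed ROIs land between the two anchor zones.

Cut-off recovery on a synthetic cohort drawn from the study's per-zone
distributions (2000 draws per cell, five seeds, pooling the
established-ischemia timepoints):

```r
rec <- recoverCutoff("lspu", nPerCell = 2000, seeds = 1:5)
round(rec$mean, 3)
#>   threshold sensitivity specificity     youdenJ
#>      67.914       0.949       0.923       0.872
```

The recovered operating point sits within a few AU of the clinically
reported cut-off (69 AU) at a comparable sensitivity. The linked-mode
study emulator ties capillary lactate to perfusion through the log
link and reproduces the reported fit quality:

```r
tabs <- generateStudy(seed = 1, linkMode = "linked")
logCurveFit(tabs$lactate$lspu, tabs$lactate$lactate)
#> LogFitResult: y = 65.6 -13.8 * ln(x), n = 167
#>   R^2 = 0.6032
```

See `vignettes/perfusion-pipeline.Rmd` for the models, calibrations and
design decisions, and `runPipeline()` for the end-to-end demonstration
that writes TIFF/CSV/PNG/JSON outputs plus a reproducibility manifest.

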