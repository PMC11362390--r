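---
title: "Quantitative laser speckle perfusion analysis: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative laser speckle perfusion analysis: models, calibrations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleFlow)
```

## The problem

During bowel surgery the surgeon must join (anastomose) two well-perfused
bowel ends; joining ischemic tissue risks anastomotic leakage.  Laser
speckle contrast imaging (LSCI) infers perfusion without dye: coherent
laser light scattered by tissue forms a speckle pattern, and moving red
blood cells blur it within the camera exposure.  The local blur is
quantified by the spatial speckle contrast

$$K = \frac{\sigma}{\mu}$$

computed over a small pixel window; the faster the flow, the lower $K$.
Perfusion is then reported in laser speckle perfusion units (LSPU,
arbitrary units), displayed as a Viridis colormap, and thresholded to
separate ischemic from well-perfused tissue.  This package implements the
full quantitative chain -- speckle simulation, contrast and perfusion
mapping, ROI statistics, Youden-index cut-offs, a perfusion--lactate
calibration, and inter-observer agreement -- so that every stage can be
tested end to end without access to animal recordings.

## Speckle simulation model

`generateSpeckleStack()` synthesizes time-integrated dynamic speckle from
a `FlowPhantom`, a per-pixel map of the decorrelation time $\tau_c$ (ms;
`Inf` for static background).  The field is a spatially band-limited
complex Gaussian: white complex noise in the frequency domain restricted
to a circular pupil of cut-off $1/(2\,g)$ cycles/px, where $g$ is the
grain-size control.  Temporal dynamics use per-pixel AR(1) phasor
updates over $M$ sub-steps per exposure $T$:

$$E \leftarrow \rho E + \sqrt{1-\rho^2}\,E_{\mathrm{new}}, \qquad
  \rho = e^{-\Delta t/\tau_c},\ \Delta t = T/M,$$

which realizes a negative-exponential field correlation.  Each frame is
the mean of $|E|^2$ over its sub-steps.  For this model the expected
spatial contrast has the closed form implemented in
`expectedContrast()`:

$$K^2(x) = \beta\,\frac{e^{-2x} - 1 + 2x}{2x^2}, \qquad x = T/\tau_c,$$

with $K^2 \to \beta$ as $x \to 0$.  This closed form is the simulator's
oracle: the test suite checks that measured region contrast tracks it
within 10% over $x \in \{0.1, 0.5, 1, 5, 20, 100\}$ and decreases
strictly with flow.

### Numerical choices in the simulator

* **Sub-step count.**  The rectangle-rule integration over $M$ sub-steps
  biases $K$ upward by roughly $0.15\,(x/M)^2$ relative, so a fixed
  small $M$ cannot meet a 10% oracle tolerance at $x \approx 100$.  The
  default is therefore automatic, $M = \max(25,\ \lceil 3\,x_{\max}
  \rceil)$, which keeps the bias near 2%; `subSteps` can still be fixed
  explicitly.
* **Grain size (default 1.5 px).**  The simulator samples the field at
  pixel centers without camera pixel-area integration, so the usual
  "grain at least 2 px" sampling rule for physical cameras does not
  apply.  What does matter is the number of independent speckles inside
  the 7 x 7 contrast window: at a 2 px grain only about a dozen remain,
  and the convexity (Jensen) bias of the $1/K^2$ flow index then pushes
  zone-mean perfusion outside the pipeline's 15% end-to-end recovery
  tolerance; a 1.5 px grain keeps it comfortably inside while remaining
  well resolved.
* **Quantization (default 16-bit at mean level 100 counts).**  Low-flow
  speckle has an exponential intensity distribution; an 8-bit range at
  mean 100 clips its tail (about 8% of pixels) and visibly depresses the
  measured contrast, so the default sensor model is 16-bit.  Bit depth
  and mean level are configurable.
* **Coherence and static light.**  `beta` rescales intensity
  fluctuations about the mean so that $K^2$ scales by $\beta$ exactly;
  `staticFraction` mixes a non-decorrelating speckle field at amplitude
  level.  Both default to the ideal case (1 and 0).
* **Randomness.**  One master seed deterministically derives one
  sub-seed per frame; identical inputs give bit-identical stacks.

The phantom itself (`makeLoopPhantom()`) is a horizontal loop band over
static background with five zones -- well, left watershed, ischemic,
right watershed, well -- where $\tau_c$ is set per zone so that
$T/\tau_c$ equals the zone's target perfusion (the inverse-square
mapping gives $1/K^2 \approx T/\tau_c$ for $T/\tau_c \gg 1$) and the
watershed zones interpolate $T/\tau_c$ linearly between neighbors.  No
peristalsis, lateral motion, instrument optics or motion compensation is
modeled.

## Contrast and perfusion mapping

`contrastMap()` computes $K$ with the population (divide-by-$n$)
standard deviation over a centered odd window (default 7 x 7), treating
the window as the local speckle ensemble.  Only pixels whose full window
fits inside the frame are valid -- no padding is invented at borders --
and zero-mean windows are invalid.  The map is exactly gain-invariant.

The device literature equates its perfusion units with a windowed
contrast statistic, yet displays high values for high flow while
$\sigma/\mu$ itself *falls* with flow.  The package therefore keeps the
two steps explicit: $K$ is computed exactly as defined, and
`lspuMap()` applies a configurable transfer function, by default the
standard flow-index convention

$$\mathrm{LSPU} = \min(1/K^2,\ \mathrm{cap}), \qquad \mathrm{cap} = 200
\ \mathrm{AU},$$

with $K = 0$ mapped to the cap.  This yields values in the observed
40--100 AU range for $K \approx 0.07$--$0.16$ and is monotone
non-increasing in $K$; a `raw_contrast` mode passes $K$ through for
diagnostics.  The true proprietary transfer function of the clinical
device is not disclosed; the inverse square is a convention, not a
reconstruction.  Temporal aggregation averages per-frame perfusion maps
pixel-wise (`meanPerfusionMap()`), with validity as the conjunction of
the inputs.

## Frame selection, ROIs and group tests

Recordings are equalized to their middle 96 frames:
`selectMiddleFrames()` keeps frames $s+1, \dots, s+n$ (1-based) with
$s = \lfloor (N-n)/2 \rfloor$, sitting one frame earlier when $N-n$ is
odd -- a deterministic, documented convention.  ROIs are 60 x 60 px
rectangles; ROI statistics use all valid pixels, unweighted, and an ROI
touching invalid pixels is a data error rather than a silent partial
mean.  Because the reported summary's SD basis is a choice, the summary
carries both the sample SD across per-frame means (the headline) and
the mean within-frame pixel SD.  Artifact handling is an explicit
per-frame exclusion list, not automated detection.

`compareGroups()` implements the analysis plan's test choice: a
Shapiro--Wilk screen per group at $\alpha = 0.05$, then a two-sided
Welch $t$ test if both groups pass, otherwise a two-sided Mann--Whitney
U.  Welch rather than pooled variance is the safer default.  Two
identical constant groups return $p = 1$ with a warning.

## Cut-off estimation

`optimalCutoff()` scans candidate thresholds at the midpoints between
consecutive distinct values (plus sentinels beyond the extremes) and
maximizes the Youden index $J = \mathrm{sens} + \mathrm{spec} - 1$.
Under the perfusion convention (`below_positive`) a value strictly
below the threshold is positive (ischemic); a value exactly at the
cut-off is classified well-perfused, reading the "below the cut-off"
rule literally.  Ties on $J$ resolve to the smallest threshold
(compared with a $10^{-12}$ tolerance so floating-point rounding of
equal count fractions cannot reorder candidates), which labels the
least tissue ischemic at equal discrimination.  The implementation is
property-tested against an exhaustive brute-force scan.

`logCurveFit()` is ordinary least squares of $y$ on $\ln x$ with
intercept; the natural log is the conventional default and the base
only rescales the slope, not $R^2$.

### Which samples enter the cut-off cohort

The study derives its cut-off from anatomically ischemic versus
well-perfused tissue but does not state which timepoints entered.  The
package default pools T60 and T120 -- the timepoints at which ischemia
is hemodynamically established.  The choice is forced by internal
consistency: immediately after ligation (T0) the reported ischemic
perfusion distribution (66.8 +/- 19.4 AU) still straddles the eventual
cut-off region, and a cohort including T0 cannot produce the reported
sensitivity of 0.94 at a threshold near 69 AU, whereas the T60/T120
pooling does.  The timepoint subset is an explicit argument of
`recoverCutoff()` so other poolings remain one call away, and the
acceptance script reports the all-timepoint pooling as well.

## The study emulator

`studyDesign()` encodes the layout: 4 animals with 5, 5, 4 and 4 loops
(18 total; "three to five loops per animal" fixed to a deterministic
split), four ROIs per loop, timepoints Tm1/T0/T60/T120, and the lactate
schedule -- T0 well in all loops but watershed/ischemic in 3 loops
only, T60 complete, T120 missing one loop -- booking
$27 + 72 + 68 = 167$ records.  Loops omitted from a schedule cell are
always the highest-numbered ones (the missing T120 loop is loop 18),
keeping the tables deterministic.

`zoneDistributions()` holds the per-(zone, timepoint) truncated-normal
parameters (lower bound 0, sampled exactly by inverse-CDF).  Values the
study does not print are filled in and flagged `non_paper`:

* well-perfused perfusion at T60/T120 reuses the T0 distribution
  (perfusion in well tissue did not change significantly over two
  hours), and the unreported well baseline reuses the overall baseline
  level;
* watershed perfusion at T60 interpolates linearly on the timepoint
  index between the reported baseline and T120 endpoints
  (88.9 +/- 7.6 to 64.8 +/- 14.8 AU), giving (72.8, 12.4);
* watershed lactate at T0 (3.0 +/- 1.5 mmol/L) interpolates between the
  well and ischemic T0 levels.

Baselines are per zone: the reported 96.9 +/- 8.0 AU belongs to the
(future) ischemic areas and 88.9 +/- 7.6 AU to watershed; the well
baseline reuses 96.9 +/- 8.0 since no baseline differences between
zones were detected.

### The perfusion--lactate link

In `linked` mode lactate is generated from the same record's perfusion
value through

$$\mathrm{lactate} = b_0 + b_1 \ln(\mathrm{LSPU}) + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma_\varepsilon),$$

with $(b_0, b_1)$ solved from the two extreme printed operating cells
(well at T0: 94.7 AU, 2.2 mmol/L; ischemic at T60: 52.2 AU,
10.3 mmol/L), giving $b_1 \approx -13.6$; draws below 0.1 mmol/L are
clipped.  The default noise $\sigma_\varepsilon = 3.8$ mmol/L is a
calibration, fixed before testing: with the link anchored as above, the
between- and within-cell spread of $\ln(\mathrm{LSPU})$ across the
scheduled cohort fixes the explainable variance, and
$\sigma_\varepsilon$ is the one free parameter left to match the
study's reported coefficient of determination ($R^2 = 0.56$).  A
markedly smaller noise (e.g. 2 mmol/L) would push $R^2$ above 0.8,
inconsistent with the reported fit.  Linked mode trades marginal
fidelity for correlation structure: the well-perfused lactate spread
under the link is wider than the printed marginal SDs, which `marginal`
mode preserves instead.  $R^2$ decreases monotonically in
$\sigma_\varepsilon$, which the suite asserts.

`amplifiedCohort()` ignores the loop structure and draws `nPerCell`
independent values per cell; at 2000 per cell the empirical Youden scan
is stable enough that the recovered thresholds sit within a few AU (or
a few tenths of a mmol/L) of their asymptotic optima.  Real loops are
not independent -- repeated measures within loop and animal -- so the
amplified cohort is a device for estimator validation, not a
bootstrap of the study.

## Inter-observer agreement

Placements are compared along the loop midline: each point is projected
to its nearest point on the midline polyline (placements farther than a
50 px snap radius are data errors), and the signed arclength difference
in cm runs positive toward ischemic tissue.  `placementCategories()`
discretizes distances with right-closed bins at +/- 1 cm by default --
the 1 cm band is the study's own headline -- into toward-well / within
/ toward-ischemic, with declined placements as a dedicated category.
`cohensKappa()` computes unweighted Cohen's kappa with a seeded
percentile bootstrap CI (2000 resamples, stratified by the first
rater's label to preserve the reference marginal); with the small
sample sizes typical here an asymptotic SE would be less trustworthy.
Missing placements are excluded pairwise and reported separately.

The exact categorization behind the study's reported kappas
(0.66/0.56/0.52) is in unavailable supplemental material, so no attempt
is made to reproduce those numbers; the bins are explicit and
configurable.  `simulateObserverPlacements()` provides the synthetic
observer model used in tests: placements drift
$N(0.6\ \mathrm{cm},\ 0.8\ \mathrm{cm})$ toward ischemic (about
two-thirds of draws positive, matching the reported direction of
drift), with a 3% decline rate.  Multi-rater statistics (Fleiss kappa,
ICC) are out of scope.

## What the synthetic data do and do not show

The generators reproduce the study's design bookkeeping, the printed
per-cell moments, a calibrated perfusion--lactate association, and
speckle stacks whose windowed contrast follows the physics oracle.
They do not reproduce: inter-animal or within-loop correlation
(amplified cohorts are i.i.d. per cell), motion artifacts or the
device's proprietary motion compensation, camera pixel-area
integration, the real contrast-to-LSPU transfer function, or the exact
observer categorization.  Passing tests therefore validate the
estimators and the pipeline plumbing under the stated distributional
conditions -- not the clinical claims themselves.

## Problem sizes used by the test suite

Simulation checks run on 128 x 128 uniform phantoms (one frame per flow
level) and a 160 x 400 loop phantom with 6 frames for end-to-end ROI
recovery; cut-off recovery uses 2000 draws per cell averaged over five
seeds; kappa and cut-off oracles sweep random instances of up to 30
points.  These sizes keep the default suite interactive while leaving
every statistical tolerance dominated by the estimator, not the sample
size.

## Known limitations

* The inverse-square perfusion mapping is a convention standing in for
  an undisclosed device transfer function; absolute AU comparisons with
  the clinical device are not meaningful, only relative structure.
* The watershed T60 perfusion and T0 lactate cells are interpolations,
  flagged as such, and any analysis leaning on those two cells inherits
  that assumption.
* The simulator's per-pixel AR(1) model has no spatial flow coupling:
  $\tau_c$ is piecewise constant per pixel and speckle decorrelates
  independently per pixel.
* Reported systemic lactate ranges in the source material are
  internally inconsistent with normal physiology and are not emulated.
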