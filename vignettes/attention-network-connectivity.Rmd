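---
title: "Methods: simulating and analyzing attention-network connectivity with training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing attention-network connectivity with training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnfc)
```

## The study design this package models

`attnfc` implements the analysis machinery of a multi-session perceptual-learning
design: three stimulation groups (active parietal stimulation, an active control
over hMT+, and Sham) of 10 subjects each train for four days on two randomly
interleaved attention tasks — orientation discrimination (OD) and temporal order
judgment (TOJ) — at individually thresholded stimulus offsets, with resting-state
fMRI collected before and after training. The primary neural readout is
resting-state functional connectivity (rs-FC) among the 10 nodes of the
dorsal-ventral attention network (DVAN: bilateral IPS, hMT+, FEF, TPJ, VFC),
with a 10-node default-mode network (DMN) as a negative control. Resting runs
are 120 volumes at TR = 2.0 s.

Because every inferential component is exercised on synthetic data with known
ground truth, the package pairs the analysis battery with a first-class
generator module: cohorts, ROI BOLD time series with a target correlation
structure, six-parameter head-motion traces, rendered 4D volumes, and
psychometric observers.

## The synthetic BOLD model

`simulateRoiTimeSeries()` draws i.i.d. Gaussian innovations, colours every ROI
channel with the *same* AR(1) recursion (lag-1 coefficient `arCoeff`, default
0.3), and mixes channels through the Cholesky factor of the target correlation
matrix. Because an identical linear filter applied to every channel commutes
with the instantaneous mixing, the cross-ROI correlation of the output equals
the target exactly in expectation while each channel carries realistic temporal
autocorrelation. Targets must be valid correlation matrices; a non-PSD target
is rejected with its smallest eigenvalue named.

Stimulation effects are injected in Fisher-z space: `applyZIncrement()` moves
every unique edge by `deltaZ` (`r' = tanh(atanh(r) + deltaZ)`); if the result
leaves the PSD cone it is repaired by eigenvalue clipping
(`nearestPSD()`) and the *achieved* post-repair increments are returned, so
recovery tests compare against what was actually injected.
`injectConnectivityEffect()` confines the increment to one group, one session
and one network — emulating the finding that connectivity increased within the
attention network after parietal stimulation only.

What the generator deliberately does **not** model: hemodynamic convolution for
resting data, cardiac/respiratory physiological noise, scanner drift beyond a
linear trend, and image registration. Passing recovery tests therefore shows
the *analysis chain* is correct and calibrated, not that it is robust to every
artifact of real acquisitions.

Defaults follow the study conditions: 3 groups x 10 subjects x 2 sessions, 120
frames, TR 2.0 s, exchangeable base correlation r = 0.25 within each network
(a typical within-network resting coupling), effect `deltaZ = 0.3` on DVAN
edges of the Parietal group in session 2.

## Preprocessing: censoring-aware cleaning

The cleaning pipeline mirrors standard motion-denoising practice and enforces
its canonical order (a step refuses to run after any later step has been
recorded):

1. **`dropInitialVolumes()`** — the first 4 volumes are removed
   (non-steady-state magnetization), leaving 116 of 120 frames.
2. **`regressNuisance()`** — least-squares projection onto 12 motion
   regressors (six rigid-body parameters and their backward-difference first
   derivatives) plus a ventricle global-signal regressor and an intercept.
   Residual orthogonality to the design is tested to 1e-8.
3. **`detrendSeries()`** — per-ROI removal of the best-fit line.
4. **`computeCensoring()`** — framewise displacement
   `FD(t) = sum |d trans| + 50 mm * sum |d rot|` (rotations in radians);
   frames with FD > 0.5 mm are censored. The 0.5 mm frame threshold is a
   common scrubbing convention (the qualitative criterion "movement-related
   activity" needs a declared number) and is configurable. A run is discarded
   outright when any single-frame change in any of the six dimensions exceeds
   3 mm.
5. **`lssdInterpolate()`** — censored frames are temporarily replaced by the
   prediction of a least-squares spectral fit to the retained frames so that a
   uniform-sampling filter can be applied.
6. **`bandpassSeries()`** — zero-phase Butterworth band-pass, 0.009–0.08 Hz.
7. **`applyCensorAndRetention()`** — censored (interpolated) frames are
   removed, and a run is kept only if the retained data span at least 180 s
   (3 minutes, boundary inclusive).

Retained-frame counts and discard flags are always reported
(`preprocessRun()$censorReport`), so censoring can never bias downstream
statistics silently — group-by-session equivalence of censored-frame counts is
itself testable with the same ANOVA machinery.

### Numerical choices in the spectral interpolation

The interpolation basis is a sine/cosine grid with spacing
`1/(oversampling * T)` (oversampling 8 over the run length `T`), solved by
minimum-norm least squares (SVD). The grid is capped at 1.25 x the band-pass
upper edge rather than extending to Nyquist: an oversampled *full-band* frame
evaluated on a near-complete regular grid degenerates into a delta comb — it
reproduces the retained samples exactly while predicting ~0 at the censored
frames. Restricting the basis to (a margin above) the passband makes the
interpolant smooth and essentially exact for in-band content (relative error
~1e-7 for an in-band sinusoid with 5 censored frames), and content above the
cap is irrelevant because the band-pass filter follows immediately. With an
empty censor mask the step is an exact no-op, so interpolate-then-filter
equals direct filtering identically.

Two safeguards keep the fit an interpolant rather than an extrapolant. The
SVD solution truncates singular values below 1e-6 of the largest, and
predictions are clamped column-wise to the range of the retained data: near
the retained-span boundary the trigonometric least-squares problem becomes
ill-conditioned and unclamped predictions can reach hundreds of standard
deviations, which would dominate the subsequent filtering of every frame.
Censored frames before the first or after the last retained frame take the
nearest retained value. (Interpolated frames are deleted before any
statistic is computed in any case; these policies only control leakage into
retained frames through the filter.)

A residual caveat of the narrow passband itself: ~116 frames of 0.009–0.08 Hz
signal carry only ~30 effective degrees of freedom, so edge-level Fisher z
estimates are noisy and carry the classic small-sample positive bias of
`atanh` (group-mean ΔFC overshoots an injected 0.3 by ~0.02 under the
default conditions). Recovery tests on the full preprocessed path use a
Monte-Carlo confidence interval, and the unfiltered path recovers the
injected increment without this bias.

The band-pass is an order-2 Butterworth applied forward and backward
(`signal::filtfilt`; the double pass squares the magnitude response and
cancels phase). Series are demeaned and reflect-padded by up to 100 frames
before filtering to suppress edge transients, which are otherwise substantial
at the very low 0.009 Hz edge. Probe-sinusoid gains: ~1.00 at 0.03 Hz,
< 0.1 at 0.2 Hz, ~0 at DC, monotone across both transition bands.

## Connectivity

`extractRoiTimeseries()` averages all voxels whose centers lie within the
6-mm sphere radius of an ROI centroid (world coordinates via the NIfTI affine,
0-based voxel indices). Center-in-sphere membership keeps ROI size identical
across subjects. `connectivityMatrix()` computes pairwise Pearson correlations
over retained frames and stores both r and Fisher z = atanh(r); for 10 ROIs
the upper triangle holds the 45 unique edges. Edges with |r| = 1 raise an
error by default (infinite z); an optional clip at 1 - 1e-7 is available.

Network summaries average *z*, not r (`networkMean()`), matching the practice
of transforming before any statistics; `deltaFC()` is the elementwise
session-2-minus-session-1 difference in z space; `groupAverage()` always
averages within subject first, then across the subjects of a group. Matrices
are tagged with their ROI-set label and cross-set operations raise.

## Psychophysics

The thresholding procedure is a 3-down-1-up staircase on same/different
judgments: one error makes the trial easier (offset up one step), three
consecutive correct responses make it harder (offset down one step);
a reversal is logged whenever the movement direction flips and the run stops
at 30 reversals (safety cap 400 trials; unstated in the original procedure,
declared here). Start level and step size are configurable; defaults start at
an easy suprathreshold level with a fixed linear step.

A 3-down-1-up rule converges where p(correct) = 0.5^(1/3) ~ 79.4%, yet the
threshold of interest is the point of subjective equality (PSE), where
"different" is reported 50% of the time. The package keeps both readings
explicit rather than conflating them:

* `method = "reversal"` — mean of the last 8 reversal levels; tracks the
  79.4% convergence point (verified against the closed-form inversion of the
  observer model).
* `method = "pse"` (default) — a probit GLM fitted to the full trial log;
  its 50% point is the PSE. Validation trials at this estimate yield ~50%
  accuracy, the design's stated calibration target.

The observer model is a cumulative Gaussian anchored so that
p("different") = 0.5 at the PSE, with optional lapse and guess rates
(bounded at 0.2); on "same" trials the model is evaluated at offset 0,
giving the false-alarm rate. OD and TOJ observers are simulated
independently; a shared attention resource across the interleaved tasks is
not modeled.

`buildSession()` constructs the cross-task session: 120 standard trials per
task at the threshold offsets (half "same", half "different"), randomly
interleaved within blocks, test side balanced left/right per task, plus 6
easy catch trials per block (~20 degrees OD, ~150 ms TOJ). The default is 4
blocks so the session totals match the printed 240 standard + 24 catch
trials, which we treat as the authoritative constraint; the block count is
configurable. `scoreSession()` reports per-task accuracy, catch accuracy, and
flags subjects whose catch performance cannot be distinguished from chance
(one-sided binomial test) for exclusion. Improvement is post minus pre, sign
preserved.

Behavioral cohorts follow a linear drift in logit-accuracy per training day
(the minimal monotone learning curve), with binomial trial noise at 120
trials per session; the default rates give an OD improvement for the Parietal
group only (~0.35 logits/day, i.e. ~30 percentage points over four days from
a 50% baseline) with TOJ flat everywhere.

## Statistics

The battery is implemented from the sums of squares up (and is verified
against `aov(Error())`, `mauchly.test`, and `car::leveneTest` as independent
oracles in the test suite):

* `oneWayAnova()` — classical F with df (k-1, N-k) and partial eta squared;
  when Levene's test rejects (or on request) the Brown-Forsythe F-ratio with
  Satterthwaite denominator df is reported and used.
* `mixedRmAnova()` — balanced split-plot decomposition: group tested against
  subjects-within-groups; the within effect and interaction against the
  subject-by-within residual. With k > 2 within levels, Mauchly's W is
  computed on the pooled within-group covariance (chi-square df
  k(k-1)/2 - 1) and, when it rejects at 0.05 (policy configurable),
  Greenhouse-Geisser epsilon multiplies the within/interaction dfs. Epsilon
  uses the orthonormal-contrast form, bounded in [1/(k-1), 1], exactly 1 for
  k = 2 and under compound symmetry. Note the standard corrected p
  (`pf(F, eps df1, eps df2)`) exceeds the uncorrected p in the consequential
  F > 1 regime but not necessarily when F < 1.
* `pairwiseTTests()` — all pairwise comparisons, Welch-Satterthwaite df for
  independent samples, Cohen's d (pooled-SD or paired mean(diff)/sd(diff),
  negative when the first mean is lower), Bonferroni multiplication capped at
  1. Two-sided throughout.
* `fcBehaviorRegression()` — simple OLS with intercept; R-squared equals the
  squared Pearson correlation by construction and the slope p is the usual
  t-test.
* `bonferroniAdjust()` / `fdrBH()` — min(1, m p) and the Benjamini-Hochberg
  step-up (verified against the exhaustive definition).

An edge-level analysis that treats all 45 edges per subject as observations
can be assembled from `groupAverage()`'s long table; the within-subject edge
dependence that this pooling ignores is the analyst's to weigh — the
within-subject-first averaging is the package's default summary.

## FIR task GLM

`buildFirDesign()` places one predictor per (condition, lag) — 10 lags per
condition at the 20 s / 2 s defaults — plus intercept and linear-drift
baseline columns. `fitFirGlm()` is plain least squares with explicit
rank-deficiency errors. `contrastPeak()` averages the four lag betas
bracketing the hemodynamic peak at ~4 s post-onset; "four volumes
surrounding a 4-s peak" is ambiguous on a 2-s grid, and the default resolves
the tie toward the later window, lags {1,2,3,4} = 2-8 s (configurable), which
covers the rise and fall of a canonical response rather than the pre-onset
frame. `thresholdMap()` applies BH-FDR at q = 0.05.

## Orchestration and reproducibility

`runPipeline()` runs simulate → preprocess → connect → test end to end from a
single `runConfig()` (YAML-serializable, one master seed); identical configs
reproduce identical outputs, and `reportTables()` flattens every tested
effect into the conventional F/df1/df2/p/partial-eta-squared layout. The
package is a library: its functions, this vignette, and
`scripts/acceptance.R` are the intended entry points rather than a shell
tool.

## Problem sizes used in the checks

The test suite exercises the battery at the design's own sizes where that is
what is being checked (3 x 10 x 2 cohorts, 120-frame runs, 45-edge matrices)
and at reduced Monte-Carlo scales chosen for stable statistics: 100 replicate
cohorts for delta-recovery (Monte-Carlo CI on the group-mean ΔFC), 2000 null
replicates for the interaction type-I calibration (binomial SE ~0.5
percentage points), 200 staircase replicates for the convergence-point
oracle, 50 observers x 500 trials for threshold validation, and 25 replicate
runs for FIR profile recovery. The null calibration generates network-mean
values directly as i.i.d. Gaussians — a valid null for the interaction test —
rather than full time-series cohorts; the delta-recovery check runs the real
series → correlation → ΔFC path.

## Known limitations

* DMN ROI centroids are synthetic placeholders at literature-typical
  locations (the source design names the regions without printing
  coordinates); they ship in `inst/extdata/dmn_rois_synthetic.tsv` and
  should be overridden for any real analysis.
* The generator's stationary-Gaussian, HRF-free resting signal cannot expose
  artifacts that arise from hemodynamic or physiological structure.
* The mixed ANOVA requires complete balanced designs; no imputation is
  offered, and unbalanced cohorts (after run exclusions) are trimmed to the
  smallest group by `runPipeline()`.
* Graph-theoretic summaries, sliding-window FC and partial correlations are
  out of scope by design.
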