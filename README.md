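# attnfc

Simulation and analysis of multi-session attention-training studies with
resting-state fMRI readouts.

## The problem

Perceptual-learning studies that pair behavioral training with noninvasive
brain stimulation ask two linked questions: did training change behavior in a
group-specific way, and did it change the brain's resting functional
organisation where the stimulation was targeted? Answering them requires a
chain of specialised machinery — adaptive psychophysical thresholding,
motion-aware cleaning of BOLD time series, seed-based network connectivity,
and a repeated-measures inferential battery — each link of which can silently
bias the result. `attnfc` implements that chain as a tested R package and
pairs it with synthetic-data generators whose ground truth is known exactly,
so every link can be validated: effects you inject are recovered where you
injected them, and nowhere else.

The package is for methodologists and analysts working with designs like:
three stimulation groups (parietal, an active control site, Sham) of 10
subjects, four days of training on two interleaved attention tasks
(orientation discrimination, OD, and temporal order judgment, TOJ) at
individually thresholded offsets, with 120-volume resting-state runs
(TR = 2.0 s) before and after training.

## What it computes

* **Connectivity.** ROI time courses are averaged over 6-mm spheres at the 10
  dorsal–ventral attention network (DVAN) centroids (bilateral IPS, hMT+,
  FEF, TPJ, VFC) and a 10-node default-mode (DMN) control set. Edges are
  Pearson correlations over retained frames, Fisher-transformed
  (z = atanh r); 45 unique edges per 10-ROI network; network mean
  z̄ = mean of the upper triangle; change Δz = z(S2) − z(S1).
* **Preprocessing.** Drop 4 initial volumes; regress 12 motion regressors +
  ventricle signal; detrend; scrub frames with framewise displacement
  FD(t) = Σ|Δd| + 50 mm·Σ|Δθ| > 0.5 mm; fill censored frames by a
  least-squares spectral fit; zero-phase 0.009–0.08 Hz band-pass; delete
  censored frames; keep runs with ≥ 180 s of data (runs with any
  single-frame motion > 3 mm are discarded outright).
* **Statistics.** Split-plot ANOVA (group × session) with Mauchly sphericity
  test and Greenhouse–Geisser df correction; one-way ANOVA with
  Brown–Forsythe robust F; pairwise t-tests with Welch df, Cohen's d and
  Bonferroni adjustment; OLS connectivity–behavior regression; BH–FDR.
* **Psychophysics.** A 3-down-1-up staircase terminating at 30 reversals;
  thresholds as the point of subjective equality (PSE, the 50% point of a
  probit fit to the trial log) or the reversal mean (which tracks the
  0.5^(1/3) ≈ 79.4% convergence level); cross-task sessions of 240 standard
  + 24 catch trials; accuracy scoring with chance-level catch exclusion.
* **FIR GLM.** Deconvolution design with one predictor per volume per
  condition over a 20-s window (10 lags at TR 2 s), peak contrast over the
  four lags around the ~4-s hemodynamic peak, FDR-thresholded maps.

## Worked example

Simulate the full study — a 3 × 10 × 2 cohort with a Fisher-z increment of
0.3 injected on the DVAN edges of the Parietal group in session 2 — run the
complete preprocessing and analysis chain, and print the report:

```r
library(attnfc)
res <- runPipeline(runConfig(seed = 42))
reportTables(res)
#>              analysis       effect       F df1 df2        p  petaSq correction
#> 1           rsFC_DVAN        group 27.0806   2  27 3.53e-07 0.66733       none
#> 2           rsFC_DVAN       within 25.7637   1  27 2.48e-05 0.48828       none
#> 3           rsFC_DVAN group:within 17.2032   2  27 1.52e-05 0.56031       none
#> 4            rsFC_DMN        group  0.6507   2  27 5.30e-01 0.04598       none
#> 5            rsFC_DMN       within  0.0716   1  27 7.91e-01 0.00264       none
#> 6            rsFC_DMN group:within  1.1185   2  27 3.41e-01 0.07651       none
#> 7 behavior_OD_prepost        group 26.8695   2  27 3.78e-07 0.66559       none
#> 8 behavior_OD_prepost       within 58.2686   1  27 3.28e-08 0.68335       none
#> 9 behavior_OD_prepost group:within 55.2506   2  27 2.86e-10 0.80364       none

aggregate(meanDelta ~ group + network, data = res$deltas,
          FUN = function(x) round(mean(x), 3))
#>      group network meanDelta
#> 1      hMT     DMN    -0.039
#> 2 Parietal     DMN     0.005
#> 3     Sham     DMN     0.055
#> 4      hMT    DVAN    -0.004
#> 5 Parietal    DVAN     0.291
#> 6     Sham    DVAN     0.047
```

Reading the output: the group-by-session interaction on mean DVAN
connectivity is strong (F(2, 27) = 17.2, p < 0.001, partial eta squared
0.56) while the same test on the DMN control network is null — the pipeline
detects the injected effect exactly where it was placed, and the
group-mean Δz for the Parietal group (0.291) recovers the injected 0.3.
The behavioral battery shows the OD pre/post interaction produced by the
Parietal-only learning curve. Degrees of freedom (2, 27) are the signature
of the 3-group, 10-per-group design.

The staircase side:

```r
obs <- observerModel(pse = 2, slope = 1)       # PSE 2 deg, SD 1 deg
sc  <- runStaircase(obs, staircaseConfig(startLevel = 8, stepSize = 1),
                    seed = 1)
sc$estimate$value        # 2.124  (PSE estimate from the probit fit)
sc$estimate$nReversals   # 30     (termination criterion)
validateThreshold(obs, sc$estimate$value, nTrials = 500, seed = 2)$accuracy
#> 0.55                   (~50% by design at the PSE)
```

## Notes

* DMN ROI coordinates shipped in `inst/extdata/dmn_rois_synthetic.tsv` are
  synthetic placeholders (see the methods vignette); override them with
  study coordinates for any real analysis.
* The methods vignette (`vignettes/attention-network-connectivity.Rmd`)
  documents the generative model, every tunable parameter, numerical
  safeguards in the spectral interpolation, and known limitations.
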