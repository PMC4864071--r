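---
title: "DTW-spectra and trial-wise measures of neural dynamics: methods and design"
author: "dtwspectrum maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTW-spectra and trial-wise measures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtwspectrum)
```

## The problem

Alternating task and rest blocks produce EEG whose moment-to-moment
*predictability* differs between cognitive states. This package implements a
family of trial-wise scalar measures of those dynamics, extracted from the
one second of signal immediately preceding each trial marker, and a
statistical layer that asks whether each measure can be cross-predicted from
the others at the group level.

The six measures per trial are:

* `dtw_sd` — the standard deviation of the **DTW-spectrum** (the package's
  core method, below);
* `dft_sd` — the standard deviation of a direct DFT power spectrum on the
  same frequency grid;
* `sse` — the one-step prediction error of a small MLP;
* `ms_length` — the length of the EEG microstate active at trial time;
* `mean_gfp` — the mean global field power over that microstate;
* `ava_length` — the length of the neuronal avalanche/cascade at or just
  before the trial.

## The DTW-spectrum

Dynamic time warping aligns two sequences by a monotone path through their
pairwise local-cost matrix, minimizing the cumulative cost; a Sakoe-Chiba
band `|i - j| <= w` bounds how far the alignment may stray from the
diagonal. The DTW-spectrum sweeps a bank of unit-variance sinusoids with
linearly increasing frequency (8–13 Hz by default) across the standardized
pre-trial segment and records, per frequency, the banded DTW distance. A
low value means the segment is well aligned to that frequency — so the
curve is roughly an upside-down power spectrum, and across alpha-dominated
segments the Spearman correlation between the DTW- and DFT-spectra is
strongly negative (typically around −0.55 at the default settings; the
acceptance script recomputes this).

Key numerical choices:

* **Band half-width 20 samples** (`window = 20`) at 50 Hz / 50-sample
  segments. The band makes the sweep fast and bounds temporal distortion.
* **Both segment and template are z-standardized** (zero mean, unit sample
  variance) before alignment, so frequency content rather than amplitude
  drives the minimum. `standardize = FALSE` restores raw-amplitude
  comparison.
* **Local cost `abs`** by default, `squared` as an option; distances are
  raw cumulative costs (no path-length normalization) because the template
  bank is fixed-length, so normalization cannot change which frequency wins.
  `normalize = TRUE` divides by `n + m` for cross-length comparisons.
* **Template phase is 0** at the first sample. Warping absorbs phase
  offsets only partially: with a 20-sample band, a noiseless sine of
  arbitrary phase lands on the exact grid bin in roughly 6 of 10 cases,
  and on the nearest-or-adjacent bin almost always. The frequency-recovery
  guarantees exercised by the tests therefore use phase-matched probes;
  treat single-bin resolution at arbitrary phase as approximate.
* **Frequency step 0.1 Hz** by default (the grid is linear; the band edges
  are inclusive when the step divides the band).
* A degenerate (constant) segment has no defined spectrum and errors out.

The matched DFT spectrum is evaluated by direct projection (naive
summation) on exactly the template grid rather than an FFT on padded data,
so the two spectra are bin-aligned for correlation and for the GLMs. Each
spectrum is condensed to its standard deviation — a peakedness summary that
is invariant to adding a constant to all bins.

## MLP predictability

A single-hidden-layer perceptron (tanh hidden layer of the same size as the
input, linear output) predicts the next sample of one channel from the 41
preceding samples (40 lags). Training uses plain gradient descent over
consecutive batches of 50 examples, 200 epochs, learning rate 0.05, with
parameters initialized uniformly at `±1/sqrt(fan-in)` from a seed. If the
final training SSE exceeds half the SSE of the constant-mean predictor the
model is re-initialized from the next seed (at most 10 times); this
relative threshold is scale-free. Separate models are trained per condition
— the first task block and the second rest block (the designated training
blocks) — and every trial of a condition is scored by its condition's
model as the sum of squared one-step errors over the trial's 1 s window.
The signal is z-scored with statistics of the training trials' windows
only, so test data never leaks into scaling or training; note that
training-block trials are scored in-sample so that the per-trial measure
table is complete.

## Microstates

Global field power is the population standard deviation across channels at
each sample. Topographies at strict interior GFP maxima are pooled across
subjects and clustered by a polarity-invariant k-means (dissimilarity
`1 − |spatial correlation|`, maps average-referenced and unit-norm,
k = 12 by default, 10 seeded restarts, 100 iterations, empty clusters
re-seeded from the worst-explained map). Each sample is then back-fitted to
the map with the highest absolute spatial correlation (ties to the lowest
index). The per-trial measures are the length of the maximal run of
identical labels containing the trial sample and the mean GFP over that
run (`gfpPower = TRUE` averages GFP² instead; mean GFP is the default
reading of "mean GFP power"). The per-subject labelling pass that some
microstate pipelines insert before group clustering is omitted: pooling
the GFP-peak maps directly feeds the same data to the group clustering.

## Avalanches

Each channel is z-scored; an event is the onset sample of each maximal
excursion beyond the threshold (two-sided by default; `perSample = TRUE`
marks every suprathreshold sample). Samples are partitioned into bins of 2,
and a cascade is a maximal run of consecutive occupied bins. The threshold
is selected from {3.2, 3.5, 3.7} SD so that the cascade count is closest
to the trial count (ties to the stricter threshold); rather than literally
down-sampling cascades to the trial count, each trial is assigned the
length of the cascade containing its bin, else the most recent cascade
before it, else 0. Cascade length is reported in bins, with the event
count as an extra column.

## Statistics

Within each condition, each measure is regressed (OLS, intercept included)
on the other five, z-scored within subject; the per-subject coefficients
are tested against zero with a one-sample t-test across subjects.
Benjamini–Hochberg FDR at α = 0.05 is applied over the 30 off-diagonal
(target, predictor) cells of a condition's matrix — the family choice
mirrors the per-condition heatmap layout. The permutation null shuffles
the *target's* trial order within each subject (preserving the predictor
covariance), refits every GLM, and recomputes the group t;
`p = (1 + #{|t*| ≥ |t|}) / (nPerm + 1)` with `nPerm = 5000` by default.
Pipeline repetitions (`n` independently seeded re-runs of the stochastic
steps) are averaged at the beta level per subject before the t-test;
`runComparison()` accepts a list of repetitions and reduces to a single
pass when given one. BOLD-style network courses, when supplied, become
extra GLM targets regressed on HRF-convolved, TR-resampled trial-measure
regressors (canonical double-gamma kernel: gamma-difference with mean lags
6 s and 16 s, undershoot ratio 1/6, 32 s support, unit peak). Permutation
p-values are reported as `NA` for BOLD cells: the trial-shuffling scheme is
defined for the trial-measure matrices, and re-convolving per permutation
would be a different test.

## The synthetic generator

`simulateSubject()`/`simulateStudy()` emulate the study layout every
measure expects: 15 subjects, five alternating 60 s task/rest blocks at
50 Hz, 112 trials (23/23/22/22/22, evenly spaced, clear of the window
margins), 32 channels. The signal is a sum of

* a planted microstate sequence: 4 orthonormal average-referenced maps
  with geometric dwell (mean 80 ms), amplitude-modulated by a smooth
  positive envelope (amplitude 0.5 by default);
* a 10 Hz alpha sinusoid with slow random phase drift
  (per-sample increments, SD 0.03) and block-dependent amplitude — 0.8 in
  task, 1.0 in rest — spatially loaded per channel
  (loadings `|N(1, 0.15)|`: the analysis channel is one where alpha is
  clearly expressed, as one would choose in practice);
* 1/f-shaped background noise with block-dependent SD — 0.3 in task, 1.2
  in rest;
* rare multi-channel transients (Poisson, 0.1/s) of amplitude 6× the local
  noise SD with shared per-channel loadings, which the avalanche detector
  picks up coherently.

The rest blocks carry both more alpha and considerably more broadband
noise, so the task state is more one-step-predictable *by construction* —
the generator reproduces the qualitative task/rest ordering as a designed
property and makes no claim about real physiology. The mixture weights
matter: the microstate component switches maps every few samples and is
one-step-unpredictable, so if it dominates the low-noise task blocks it can
invert the designed ordering; the default weights (state 0.5 vs task noise
0.3) keep the construction valid with a wide margin.

Two presets isolate single properties: `microstateFixture()` (state/noise
ratio 3, white sensor noise — the standard microstate-simulation
convention — alpha and transients off) for topography recovery, and
`alphaBurstSegments()` (alpha amplitude 1 against 1/f background SD 0.3,
random phase and drift) for the inverted-spectra property.
`generateNullMeasures()` emits six mutually independent normal measure
columns (shifted by +10 to satisfy the nonnegativity of real measures; a
shift changes no statistic) as the exchangeable null for calibration, and
`generateBOLD()` builds coupled network courses for the BOLD branch.

What the generator does **not** emulate: volume conduction from dipolar
sources (maps are random orthonormal vectors, not forward-modelled
topographies), heavy-tailed artifact structure, non-stationary alpha peak
frequency, 1/f slope variation, or any haemodynamic physiology beyond the
canonical kernel. Passing tests on this substrate demonstrate correctness
and calibration of the algorithms, not empirical claims about real EEG.

## Problem sizes and determinism

Every stochastic function takes a `seed` and restores the caller's RNG
state. The test-suite and the acceptance script run at deliberately modest
problem sizes — e.g. exhaustive DTW enumeration up to length 8, 10-seed
recovery batteries, 300 calibration repetitions at 200 permutations —
chosen so the whole battery completes in minutes on one CPU while leaving
the statistical margins wide (binomial SE at those sizes is a few percent).
The defaults inside the package (5000 permutations, k = 12, 20
repetitions) are the analysis-scale settings.

## Known limitations

* DTW frequency resolution at arbitrary phase is ~1 bin at a 0.5 Hz grid;
  sub-bin claims need phase-matched templates or denser grids.
* The DTW-spectrum's SD, like the DFT's, confounds oscillation prominence
  with spectral shape; the package deliberately reports the SD reduction
  and leaves interpretation to the analyst.
* `fitTrialGLM` requires a full-rank design; near-duplicate measures (for
  example `dtw_sd` and `dft_sd` on very clean oscillations) can make the
  group betas unstable even when technically full-rank.
* The avalanche threshold grid {3.2, 3.5, 3.7} is the conventional range,
  but on recordings whose cascade counts sit far from the trial count all
  candidates are poor; `selectThreshold` still returns the closest and
  reports the gap implicitly via the cascade count. On the default
  synthetic substrate this is the typical situation: its channels carry
  independent near-Gaussian backgrounds, so suprathreshold excursions are
  far more numerous than on spatially correlated real EEG and the selector
  lands on the strictest candidate with a large residual gap. The
  count-matching step is exercised by constructed fixtures instead.
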