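---
title: "Methods: automated AP metrics from optically mapped cardiac microtissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated AP metrics from optically mapped cardiac microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cardiomap analyzes voltage-sensitive-dye recordings of hiPSC-derived 3D
cardiac microtissues for cardiotoxicity screening. A single field of view
images a 4x4 grid of microtissues at 1000-2000 frames/s; the package turns
such a movie into per-tissue, per-beat action-potential (AP) shape metrics,
and complements the experimental pipeline with an in-silico
population-of-models study of selective ion-channel block. This vignette
records the models, the tunable parameters, and the design decisions, so a
user knows what the defaults mean and what the tests do and do not
demonstrate.

## Segmentation: spectral amplitude, thresholding, labeling

Raw fluorescence snapshots have poor contrast: agarose molds absorb dye, and
illumination and staining vary across the field. Pixels that carry APs are
instead recognized in the frequency domain. Each pixel trace is linearly
detrended (removing the mean and the dominant bleaching trend so that
constant offsets can never contribute) and Fourier transformed; the pixel's
value in the *spectral amplitude image* is the maximum un-normalized DFT
magnitude over the bins inside the pacing band. The default band is
`[0.5, 1.5] x f_pace` with `f_pace = 1000/pacingCL` Hz: a proportional band
tolerates drift in spontaneous rate, and whether to admit harmonics is a
free choice -- the default includes only the fundamental's neighborhood and
is configurable through `band`.

Two histogram thresholds are implemented on this image (256 bins by
default, ties broken toward the lowest qualifying threshold):

* `otsuThreshold` minimizes the weighted within-class intensity variance;
* `minCrossEntropyThreshold` minimizes the Li-Lee cross entropy
  `-sum(g<=t) g h(g) log(mu_low) - sum(g>t) g h(g) log(mu_high)`, which
  requires positive intensities (images are shifted up and the threshold
  shifted back when needed).

The minimum-cross-entropy criterion is the default because the variance
criterion is conservative on these images: dim tissue rims fall below the
Otsu threshold, clipping regions. Connected components (8-connected by
default) above `minArea = 20` px survive; with ~800 um tissues at ~50 um/px
a tissue disk is roughly 200 px, so 20 px rejects speckle without touching
real tissues. Labels are assigned in raster order of the centroids, and each
region's trace is the frame-wise arithmetic mean over its pixels, which
suppresses i.i.d. pixel noise by about `1/sqrt(n_pixels)`.

## Baseline removal and dF/F0

Dye bleaching and perfusion-level fluctuation produce slow drift. The
baseline is fitted with an iteratively reweighted ("asymmetric least
squares") polynomial: the trace is decimated to `nDownsample = 512` points
(plain decimation -- only the slow baseline is wanted from the fit, so no
anti-alias filter is needed), iteration 1 is an ordinary cubic fit, and in
each later iteration samples above the current fit are down-weighted by
`p = 0.001` while samples at or below keep weight 1. Five iterations are the
default; because APs deflect strictly upward, the reweighting drags the fit
onto the diastolic baseline. A polynomial (order 3 by default, order 5 for
stronger drift) replaces a smoothness-penalty formulation deliberately: the
fit is a tiny least-squares problem instead of a banded-matrix inversion at
full resolution. The fit is one-directional on average -- more iterations
push the fitted curve down at AP plateau samples -- but not pointwise
monotone, since refitting a polynomial can locally raise it; the tests
assert the mean-level property.

Normalization is `dF/F0 = (F - F0)/F0` per timepoint, which cancels any
common gain (bleaching, illumination). It requires `F0 > 0`; cameras add a
dark offset, so `preprocessTrace(offset = )` subtracts it before dividing.
The amplitude of successive beats on a strongly bleaching synthetic
recording stays constant within 3% after normalization.

## Denoising: 1-D bilateral filter

Gaussian smoothing strong enough to help SNR blurs the AP upstroke. The
bilateral filter adds a Gaussian *range* kernel: neighbors that differ from
the center value by much more than `sigmaR` are effectively excluded from
the average, so the upstroke edge survives. Defaults: `window = 15`
samples, `sigmaS = window/4`, `sigmaR` = 30% of a robust amplitude estimate
(0.5%-99.5% quantile range). With `sigmaR -> Inf` the filter reduces
exactly to Gaussian smoothing; on an ideal step it retains >= 90% of the
step slope where the plain Gaussian of equal window keeps < 50%. The output
is always a convex combination of window values, so no overshoot is
possible.

## MAS metric extraction

All event detection uses moving-average subtraction:
`MAS = centered_moving_average(x, w) - x`, with reflect padding. At a convex
corner of the trace (AP takeoff; the late-repolarization slow-down) the
window mean exceeds the trace and MAS peaks; at a concave corner (end of the
rapid upstroke) it dips. Per beat:

* **takeoff** = MAS maximum in `[stim, stim + searchSpan]`
  (`searchSpan = 300` ms, capped at the pacing interval; ties take the
  earliest index);
* **upstroke end** = earliest MAS minimum after takeoff;
* **stimulation delay** = takeoff - stimulus; **rise time** = upstroke end -
  takeoff;
* **APD30/50/80** = earliest time after the AP peak where the trace falls
  below `peak - f (peak - baseline)`, minus the takeoff time, with
  sub-sample linear interpolation; the *subsequent baseline* is the median
  of the last `baselineWindow = 20` ms before the next stimulus;
* **APDmxr** = time of the MAS secondary maximum (repolarization window)
  after `upstroke end + 20` ms guard, the point of maximum rate change of
  repolarization; the search stops half a window before the next stimulus
  so the next beat's upstroke cannot contaminate it;
* **APDtri** = APDmxr - APD50, by definition, asserted per record;
* **excitability** = percentage of stimuli whose beat amplitude reaches
  `apDetectFrac = 0.3` of the median beat amplitude. A purely relative rule
  would declare an AP-free noise recording excitable, so beats must also
  exceed `minSnr = 5` times a robust noise estimate
  (`mad(diff(x))/sqrt(2)`).

All APDs are measured from takeoff: that makes stimulation delay and APD
independent, which is the standard electrophysiology convention. Window
sizes are stated in samples at 1 kHz (`upstrokeWindow = 45`,
`repolWindow = 91`) and rescale automatically with the sampling rate so
their physical width is preserved at 2 kHz. Rise time measured this way is
genuinely window-dependent whenever an AP has a fast segment followed by a
slow crest: the MAS minimum slides along the crest roughly in proportion to
the window. On clean single-corner upstrokes the estimate is stable across
windows 9-45, and it is always no longer than the time-to-peak rise time.
Beats whose upstroke cannot be found, or that never cross an APD threshold
before the next stimulus, carry `NA` metrics rather than fabricated values.

## The synthetic-data generator

Downstream stages are tested against movies with closed-form ground truth.
The surrogate AP (`makeWaveform`) is piecewise: linear upstroke over
`riseTime`; a power-law plateau `1 - 0.5 u^plateauShape` that crosses 50%
repolarization exactly at `apd50`; linear segments through the 80% crossing
at `apd80` down to `mxrLevel = 0.05` of the amplitude at `apdMxr`; then a
slow exponential tail (`tailTau = 40` ms). The slope discontinuity at
`apdMxr` places the late-repolarization curvature maximum exactly there, so
every metric the pipeline should recover is known analytically
(`waveformGroundTruth`; the APD30 crossing is
`riseTime + (apd50 - riseTime) 0.6^(1/plateauShape)`).

Movies place non-overlapping tissue disks on a grid and corrupt them the way
real recordings are corrupted: multiplicative exponential bleaching
(`bleachTau`, seconds), additive slow polynomial drift, a planar non-uniform
background, and i.i.d. Gaussian pixel noise (a shot-noise approximation with
directly controllable SNR). Fixed seeds give bit-identical movies, and the
generator restores the caller's RNG state. The generator does *not* emulate
contraction-motion artifacts, virtual-electrode polarization patterns, or
calcium-dye kinetics -- passing tests therefore demonstrate correctness of
the signal processing under the stated corruption model, not robustness to
motion or optical artifacts absent from it.

## The ventricular population model

The in-silico arm simulates the published human ventricular myocyte ODE
model (endocardial variant; epicardial and mid-myocardial parameter sets are
deliberately out of scope). The implementation is in C++ with Rush-Larsen
updates for the 30 gating variables and forward Euler for voltage and
concentrations, on an adaptive step bounded so each step changes voltage by
at most `dvMax = 0.75` mV (`dtMin = 0.005`, `dtMax = 0.15` ms). Halving all
three controls changes APD80 by under 1 ms, and the quiescent model drifts
by under 0.1 mV/s. Runs are deterministic.

Heterogeneity: each cell scales six conductances (`gNa/gNaL` shared, `gto`,
`pCa`, `gKr`, `gKs`, `gK1`) by independent Gaussians with mean 1, truncated
below at 0.05. The spread is specified through the *output*: the no-block
population's APD80 coefficient of variation should be about 0.10 (the
normal-QT-range analogue), so `calibrateHeterogeneity` bisects the
conductance cv on a pilot population until `SD(APD80)/mean = 0.10 +- 0.01`;
this typically lands near cv 0.13-0.15.

Pacing protocol: 20 beats at cycle length 2000 ms; the penultimate beat is
analyzed. The stimulus directly increases the voltage (a +40 mV jump), which
makes stimulation delay identically zero; a conventional current stimulus
(-80 uA/uF for 0.5 ms) is available. Cells are excluded when integration
fails, when the analyzed beat's peak stays below 0 mV (failure to initiate),
or when the voltage at the end of the analyzed diastolic interval is above
-60 mV (failure to repolarize); both thresholds are package choices and are
configurable. The analyzed beat is min-max normalized and fed through the
identical MAS machinery as experimental traces, so simulation and experiment
share one code path.

Two measurement caveats follow from the stimulus model and are worth
stating plainly. First, the voltage jump starts the AP at about -48 mV,
truncating the foot of the upstroke; under strong sodium-channel block the
remaining upstroke becomes a short fast segment followed by a pronounced
slow crest, and the MAS rise time then grows with the upstroke window
(roughly +25% change at window 13 up to several-fold at window 45 for 75%
block). Rise-time *changes* under sodium block should therefore be read as
window- and stimulus-convention-dependent; the direction and its
exclusivity to sodium block are robust, the magnitude is not. Second, the
same truncation shifts the AP peak (the APD reference point) during sodium
block, so the model-level invariance of APD50 to sodium block is asserted
under the current stimulus, where the peak is intact.

## Feature extraction and classification

Per-cell paired percent changes, `100 (blocked - reference)/reference` on
the same conductance draw, form the feature table (paired contrasts follow
from simulating each cell with and without block; for experimental tables an
unpaired population-mean reference is available). Samples with any undefined
metric are dropped and counted. Block levels 75/50/25% remaining are pooled
with equal weight. PCA standardizes features (z-scores) and decomposes the
correlation matrix; components are sign-fixed so the largest-magnitude
loading is positive. The classifier is an L2-penalized multinomial logistic
regression: 80/20 stratified split, standardization fitted on the training
set only, regularization strength tuned by stratified 5-fold CV over
`C in 10^-3..10^3` (13 log-spaced points, a package choice), and the whole
procedure repeated over independent splits (5 for large tables, 100 for
small ones) to report mean and SD accuracies.

## Problem sizes and numerical conventions

The packaged study (`simulateBlockStudy`) uses 100 cells per scenario, a
40-cell calibration pilot, and the 6-channel x 3-level sweep -- about two
thousand paced-cell simulations, a few hundred times smaller than a
full-scale population study but large enough for stable means and a
near-saturated classifier. Tie-breaks everywhere take the earliest index or
lowest threshold. Reflect padding is used by every windowed operation.
Output sampling is 1 sample/ms to match experimental acquisition.

## Known limitations

* No conduction/propagation analysis; one trace per tissue.
* No detector for early afterdepolarizations; beats with EADs will simply
  report long APDs or fail to repolarize.
* The generator's corruption model omits motion artifacts (see above).
* Only the endocardial parameter set of the ventricular model is exercised;
  hiPSC-CM-specific model variants are not included, so simulated absolute
  APDs represent adult ventricular myocytes, not microtissues.
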