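# cardiomap

Automated analysis of voltage-sensitive-dye optical mapping recordings of
hiPSC-derived 3D cardiac microtissues, for in-vitro cardiotoxicity testing.
A single camera field of view images a 4x4 grid of microtissues at 1000-2000
frames/s; `cardiomap` turns such a movie into per-tissue, per-beat
action-potential (AP) shape metrics, and pairs the experimental pipeline
with an in-silico population-of-models study of selective ion-channel block.

The pipeline, stage by stage:

1. **Segmentation** — each pixel trace is detrended and Fourier-transformed;
   the per-pixel maximum DFT amplitude inside the pacing band forms a
   high-contrast image on which individual microtissues are found by
   histogram thresholding (minimum cross entropy by default, Otsu for
   comparison) and connected-component labeling; pixel traces are averaged
   per tissue.
2. **Baseline correction** — an iteratively reweighted ("asymmetric least
   squares") polynomial fit (points above the fit weighted by p = 0.001)
   tracks drift from dye bleaching and perfusion-level fluctuation; traces
   are normalized to dF/F0 = (F − F0)/F0.
3. **Denoising** — an edge-preserving 1-D bilateral filter (Gaussian spatial
   × Gaussian intensity-range kernel) that smooths noise without blurring
   the AP upstroke.
4. **Metrics via moving-average subtraction (MAS)** — with
   MAS = moving_average(x, w) − x, the AP takeoff is the MAS maximum, the
   end of the rapid upstroke the MAS minimum, and the late-repolarization
   slow-down a secondary MAS maximum. Eight metrics per beat: stimulation
   delay, rise time, APD30/50/80 (fractional repolarization crossings,
   takeoff-referenced, sub-sample interpolated), APDmxr (maximum rate change
   of repolarization), APDtri = APDmxr − APD50, and excitability (% of
   stimuli evoking an AP).
5. **In-silico validation** — a C++ implementation of the O'Hara et al.
   human ventricular endocardial model, 100-cell populations with Gaussian
   conductance heterogeneity calibrated so SD(APD80)/mean ≈ 0.10, paced 20
   beats at CL 2000 ms; selective block of I_Na/I_NaL, I_to, I_Ca, I_Kr,
   I_Ks, I_K1 at 75/50/25% remaining conductance. Simulated beats run
   through the identical MAS pipeline.
6. **Classification** — per-cell percent-change features, PCA on the
   z-scored table, and an L2-penalized multinomial logistic regression
   (80/20 stratified split, 5-fold CV tuning, repeated splits) to identify
   the blocked channel.

## Worked example

Generate a synthetic 2x2-tissue movie with known ground truth (bleaching,
drift, non-uniform background, noise) and analyze it end to end:

```r
library(cardiomap)

spec <- MovieSpec(height = 60, width = 60, nFrames = 2500, frameRate = 1000,
                  gridRows = 2, gridCols = 2, tissueRadius = 9,
                  pacingCL = 1000, bleachTau = 20,
                  driftPoly = c(0, 0.01, -0.002), backgroundLevel = 0.3,
                  noiseSd = 0.03, seed = 7)
truth <- WaveformSpec(takeoffTime = 12, riseTime = 8, amplitude = 1,
                      apd50 = 230, apd80 = 272, apdMxr = 307,
                      restingLevel = 0.5)
mm <- makeMovie(spec, truth)
an <- analyzeMovie(mm$movie)
round(an$summary[, c("tissue", "stim_delay_ms", "rise_ms", "apd50_ms",
                     "apd80_ms", "apd_mxr_ms", "apd_tri_ms")], 1)
```

```
  tissue stim_delay_ms rise_ms apd50_ms apd80_ms apd_mxr_ms apd_tri_ms
1      1            12       8    228.8    272.0      306.0       77.2
2      2            12       8    228.6    271.6      306.5       77.9
3      3            12       8    228.7    271.5      306.0       77.3
4      4            12       8    228.6    271.6      307.0       78.4
```

All four tissues are segmented (Jaccard 1.0 against the ground-truth masks)
and every metric lands within 2 ms of its constructed value (stimulation
delay 12 ms, rise 8 ms, APD50 230, APD80 272, APDmxr 307). The same call
chain is available from the shell via `inst/cli/cardiomap.R`
(`simulate-movie`, `analyze`, `simulate-population`, `classify`).

A single simulated cell through the same metric pipeline:

```r
sim <- simulateCell(cellParams(), cl = 2000, nBeats = 20)
beatMetrics(beatTrace(sim))$summary[c("apd50_ms", "apd80_ms", "apd_mxr_ms")]
```

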