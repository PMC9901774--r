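# Shared fixtures, built in code. Heavy objects are memoized per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# reference waveform used across modules (1 Hz pacing landmarks)
ref_waveform <- function(...) {
  args <- list(takeoffTime = 12, riseTime = 8, amplitude = 1, apd50 = 230,
               apd80 = 272, apdMxr = 307, restingLevel = 0.5)
  over <- list(...)
  args[names(over)] <- over
  do.call(WaveformSpec, args)
}

# small 2x2-grid movie with bleaching, drift, background and noise
small_movie <- function() {
  memo("small_movie", {
    spec <- MovieSpec(height = 60, width = 60, nFrames = 2500,
                      frameRate = 1000, gridRows = 2, gridCols = 2,
                      tissueRadius = 9, pacingCL = 1000, bleachTau = 20,
                      driftPoly = c(0, 0.01, -0.002), backgroundLevel = 0.3,
                      noiseSd = 0.03, seed = 7)
    makeMovie(spec, ref_waveform())
  })
}

# the 4x4 grid at reduced frame size (same layout as the acquisition)
grid16_movie <- function() {
  memo("grid16_movie", {
    spec <- MovieSpec(height = 80, width = 80, nFrames = 2200,
                      frameRate = 1000, gridRows = 4, gridCols = 4,
                      tissueRadius = 7, pacingCL = 1000, bleachTau = 25,
                      driftPoly = c(0, 0.02), backgroundLevel = 0.25,
                      noiseSd = 0.03, seed = 11)
    makeMovie(spec, ref_waveform())
  })
}

# one clean single-beat trace from the reference waveform at 1 kHz
clean_beat <- function() {
  ws <- ref_waveform()
  t <- seq(0, 999, by = 1)
  APTrace(makeWaveform(ws, t), samplePeriod = 1, stimTimes = 0)
}

# jaccard index between a predicted and a truth label
jaccard <- function(pred_lab, truth_lab, i, j = i) {
  inter <- sum(pred_lab == i & truth_lab == j)
  uni <- sum(pred_lab == i | truth_lab == j)
  inter / uni
}

# direct (oracle) threshold searches over the same histogram the
# implementation uses: naive per-candidate class statistics
.oracle_thresholds <- function(x, nbins) {
  rng <- range(x)
  cuts <- seq(rng[1], rng[2], length.out = nbins + 1)
  bin <- findInterval(x, cuts, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (cuts[-1] + cuts[-(nbins + 1)]) / 2
  g <- centers[bin]
  best_otsu <- best_li <- NA
  min_wcv <- min_eta <- Inf
  for (t in seq_len(nbins - 1)) {
    lo <- g[bin <= t]; hi <- g[bin > t]
    if (length(lo) == 0 || length(hi) == 0) next
    wcv <- length(lo) * mean((lo - mean(lo))^2) +
      length(hi) * mean((hi - mean(hi))^2)
    if (wcv < min_wcv - 1e-12) { min_wcv <- wcv; best_otsu <- cuts[t + 1] }
    eta <- -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
    if (eta < min_eta - 1e-12) { min_eta <- eta; best_li <- cuts[t + 1] }
  }
  list(otsu = best_otsu, li = best_li)
}
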