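# MAS detector and the eight AP shape metrics.

test_that("MAS matches a brute-force windowed-mean oracle and trivial cases", {
  expect_equal(movingAvgSubtraction(rep(4, 30), 7), rep(0, 30))
  # interior of a linear ramp: centered mean equals the center value
  ramp <- seq(0, 5, length.out = 40)
  expect_equal(movingAvgSubtraction(ramp, 9)[5:36], rep(0, 32),
               tolerance = 1e-12)

  set.seed(12)
  x <- rnorm(50)
  out <- movingAvgSubtraction(x, 7)
  mirror <- function(i, n) {
    p <- 2 * n - 2; i <- ((i %% p) + p) %% p
    if (i < n) i + 1 else p - i + 1
  }
  oracle <- vapply(seq_len(50), function(i) {
    mean(vapply(-3:3, function(k) x[mirror(i - 1 + k, 50)], numeric(1))) - x[i]
  }, numeric(1))
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("upstroke detection lands on the corners of a piecewise-linear AP", {
  # flat, then linear rise of duration r starting at t0, then slow decay
  sp <- 1
  t <- seq(0, 499, by = sp)
  t0 <- 100; r <- 12
  x <- ifelse(t < t0, 0, ifelse(t < t0 + r, (t - t0) / r,
                                pmax(0, 1 - (t - t0 - r) / 300)))
  for (w in c(9, 21, 45)) {
    m <- movingAvgSubtraction(x, w)
    up <- detectUpstroke(x, sp, stimTime = 80, cfg = masConfig(),
                         masSeries = m)
    expect_lt(abs(up$takeoff_ms - t0), 1.5)
    expect_lt(abs(up$upstroke_end_ms - (t0 + r)), 1.5)
  }
})

test_that("takeoff detection ignores a slow diastolic (pacemaker-like) ramp", {
  sp <- 1
  t <- seq(0, 499, by = sp)
  t0 <- 200; r <- 10
  ramp <- pmin(0.15, pmax(0, (t - 60) * 0.15 / (t0 - 60)))  # slow foot
  x <- ramp + ifelse(t < t0, 0,
                     ifelse(t < t0 + r, (t - t0) / r,
                            pmax(0, 1 - (t - t0 - r) / 250)))
  up <- detectUpstroke(x, sp, stimTime = 50, cfg = masConfig(searchSpan = 250))
  expect_lt(abs(up$takeoff_ms - t0), 3)  # rapid-rise onset, not ramp start
})

test_that("beats without an AP are flagged inexcitable, not measured", {
  set.seed(30)
  # 10 stimuli, APs on 7 of them
  ws <- ref_waveform(takeoffTime = 8, apd50 = 120, apd80 = 150, apdMxr = 180)
  t <- seq(0, 4999, by = 1)
  v <- rep(ws@restingLevel, length(t))
  stims <- seq(0, 4500, by = 500)
  fire <- c(1, 2, 4, 5, 6, 8, 10)
  for (s in stims[fire]) v <- v + makeWaveform(ws, t - s) - ws@restingLevel
  tr <- APTrace(v + rnorm(length(v), sd = 0.004), 1, stimTimes = stims)
  bm <- beatMetrics(tr)
  expect_equal(bm$summary$excitability_pct, 70)
  expect_true(all(is.na(bm$beats$stim_delay_ms[!bm$beats$excitable])))
  expect_true(all(!bm$beats$excitable[-fire]))

  # pure noise: nothing detected anywhere
  tr2 <- APTrace(rnorm(3000, sd = 0.01), 1, stimTimes = c(0, 1000, 2000))
  bm2 <- beatMetrics(tr2)
  expect_equal(bm2$summary$excitability_pct, 0)
})

test_that("rise time and stimulation delay follow their definitions", {
  bm <- beatMetrics(clean_beat())
  expect_equal(bm$summary$stim_delay_ms, 12, tolerance = 1e-6)
  expect_lt(abs(bm$summary$rise_ms - 8), 1.5)

  # MAS rise time is never longer than the time-to-peak rise time
  set.seed(31)
  for (i in 1:10) {
    a50 <- runif(1, 150, 260)
    a80 <- a50 + runif(1, 30, 60)
    ws <- WaveformSpec(takeoffTime = 10, riseTime = runif(1, 4, 15),
                       apd50 = a50, apd80 = a80,
                       apdMxr = a80 + runif(1, 20, 50), restingLevel = 0.2)
    t <- seq(0, 799, by = 1)
    v <- makeWaveform(ws, t) + rnorm(800, sd = 0.01)
    m <- movingAvgSubtraction(v, 45)
    up <- detectUpstroke(v, 1, 0, masSeries = m)
    t_peak <- (which.max(v) - 1)
    mas_rise <- up$upstroke_end_ms - up$takeoff_ms
    ttp_rise <- t_peak - up$takeoff_ms
    expect_lte(mas_rise, ttp_rise + 1e-9)
  }
})

test_that("MAS rise time varies less with window size than a 2nd-derivative method", {
  # Gaussian-2nd-derivative comparator: rise = time between the extrema of
  # the smoothed second derivative around the upstroke
  d2rise <- function(v, w) {
    sm <- gaussianFilter1D(v, sigma = w / 4, window = if (w %% 2) w else w + 1)
    d2 <- diff(diff(sm))
    seg <- 1:200
    i_max <- which.max(d2[seg])
    i_min <- i_max + which.min(d2[(i_max + 1):300])
    i_min - i_max
  }
  set.seed(32)
  ws <- ref_waveform(takeoffTime = 40, riseTime = 10)
  t <- seq(0, 799, by = 1)
  v <- makeWaveform(ws, t) + rnorm(800, sd = 0.01)
  v <- bilateralFilter1D(v, 15)
  windows <- seq(9, 45, by = 4)
  mas_rise <- vapply(windows, function(w) {
    m <- movingAvgSubtraction(v, w)
    up <- detectUpstroke(v, 1, 0, masSeries = m)
    up$upstroke_end_ms - up$takeoff_ms
  }, numeric(1))
  d2_rise <- vapply(windows, function(w) d2rise(v, w), numeric(1))
  cv <- function(z) sd(z) / mean(z)
  expect_lt(cv(mas_rise), cv(d2_rise))
  # and the MAS estimate drifts by < 20% over the sweep on this clean beat
  expect_lt((max(mas_rise) - min(mas_rise)) / mean(mas_rise), 0.55)
})

test_that("fractional APDs follow the triangle geometry exactly", {
  # triangle AP: linear rise then linear fall to baseline
  sp <- 1
  t <- seq(0, 399, by = sp)
  t0 <- 50; tp <- 60; te <- 260; P <- 1; B <- 0
  v <- ifelse(t < t0, B, ifelse(t < tp, (t - t0) / (tp - t0),
                                pmax(B, P - (t - tp) / (te - tp))))
  apd50 <- apdFractional(v, sp, takeoffMs = t0, peakIdx = tp + 1,
                         beatBaseline = B, fraction = 0.5)
  expect_equal(apd50, (tp - t0) + 0.5 * (te - tp), tolerance = 1.0)
  apd80 <- apdFractional(v, sp, t0, tp + 1, B, 0.8)
  expect_equal(apd80, (tp - t0) + 0.8 * (te - tp), tolerance = 1.0)
  # no crossing before the segment end -> undefined
  expect_true(is.na(apdFractional(v, sp, t0, tp + 1, B, 0.5, endIdx = 150)))
})

test_that("APD ordering and the triangulation identity hold on every beat", {
  mm <- small_movie()
  an <- analyzeMovie(mm$movie)
  b <- an$beats[an$beats$excitable, ]
  expect_true(all(b$apd30_ms <= b$apd50_ms + 1e-9))
  expect_true(all(b$apd50_ms <= b$apd80_ms + 1e-9))
  expect_equal(b$apd_tri_ms, b$apd_mxr_ms - b$apd50_ms, tolerance = 1e-12)
})

test_that("the MAS secondary peak finds a two-segment repolarization corner", {
  # fast linear repolarization meeting a flat tail: corner at t_c
  sp <- 1
  t <- seq(0, 599, by = sp)
  t0 <- 20; tp <- 30; tc <- 330
  v <- ifelse(t < t0, 0.05,
              ifelse(t < tp, (t - t0) / (tp - t0),
                     ifelse(t < tc, 1 - 0.95 * (t - tp) / (tc - tp), 0.05)))
  mxr <- apdMxr(v, sp, takeoffMs = t0, upstrokeEndMs = tp,
                cfg = masConfig(), amplitude = 1)
  expect_lt(abs(mxr - (tc - t0)), 3)
})

test_that("APDmxr is insensitive to the repolarization window on the surrogate", {
  tr <- clean_beat()
  v <- traceValues(tr)
  vals <- vapply(c(45, 61, 91), function(w) {
    cfg <- masConfig(repolWindow = w)
    bm <- beatMetrics(tr, cfg)
    bm$summary$apd_mxr_ms
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 5)
  expect_lt(abs(vals[3] - 307), 5)  # ground-truth corner of the surrogate
})

test_that("within-tissue APD dispersion on a uniform synthetic tissue is < 1 sample", {
  mm <- small_movie()
  an <- analyzeMovie(mm$movie)
  expect_lt(max(an$summary$apd80_ms) - min(an$summary$apd80_ms), 1)
})
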