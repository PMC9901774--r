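# Baseline fitting, dF/F0 normalization, and the two smoothing filters.

test_that("the ALS fit reproduces a pure polynomial and the OLS special case", {
  t <- seq_len(2000)
  cubic <- 2 + 0.003 * t - 4e-6 * t^2 + 1e-9 * t^3
  bl <- alsBaseline(cubic, polyOrder = 3)
  expect_equal(bl, cubic, tolerance = 1e-9)

  # p = 1 never asymmetrizes: equals the ordinary least squares polynomial
  # fit computed from the normal equations on the same decimated points
  set.seed(2)
  y <- cubic + rnorm(2000, sd = 0.3)
  bl1 <- alsBaseline(y, polyOrder = 3, p = 1, nIter = 4, nDownsample = 256)
  idx <- unique(round(seq(1, 2000, length.out = 256)))
  tt <- 2 * (idx - 1) / 1999 - 1
  X <- outer(tt, 0:3, `^`)
  beta <- solve(crossprod(X), crossprod(X, y[idx]))
  tfull <- 2 * (t - 1) / 1999 - 1
  expect_equal(bl1, as.numeric(outer(tfull, 0:3, `^`) %*% beta),
               tolerance = 1e-9)
})

test_that("ALS recovers known drift under an AP train within 2%", {
  # APs occupy < 40% of the time; drift is a known cubic
  t <- seq(0, 3999, by = 1)
  drift <- 10 + 0.002 * t - 8e-7 * t^2 + 1.2e-10 * t^3
  ws <- WaveformSpec(takeoffTime = 10, riseTime = 6, amplitude = 4,
                     apd50 = 180, apd80 = 220, apdMxr = 250,
                     restingLevel = 0)
  ap <- rep(0, length(t))
  for (s in seq(0, 3000, by = 1000)) ap <- ap + makeWaveform(ws, t - s)
  y <- drift + ap
  bl <- alsBaseline(y, polyOrder = 3)
  ap_free <- ap < 1e-6
  expect_lt(max(abs(bl[ap_free] - drift[ap_free]) / drift[ap_free]), 0.02)

  # asymmetric reweighting is one-directional: on average over the AP
  # plateau, more iterations push the fit down toward the diastolic baseline
  plateau <- ap > 3
  prev <- alsBaseline(y, nIter = 1)
  for (k in 2:5) {
    cur <- alsBaseline(y, nIter = k)
    expect_lte(mean(cur[plateau]), mean(prev[plateau]) + 1e-8)
    prev <- cur
  }
})

test_that("dF/F0 normalization follows its definition and gain invariance", {
  f0 <- seq(10, 12, length.out = 100)
  expect_equal(normalizeDFF0(f0, f0), rep(0, 100))
  expect_equal(normalizeDFF0(1.05 * f0, f0), rep(0.05, 100))
  expect_error(normalizeDFF0(f0, f0 - 11), "offset")
  # common positive gain cancels
  f <- f0 + sin(seq_len(100) / 5)
  expect_equal(normalizeDFF0(3.7 * f, 3.7 * f0), normalizeDFF0(f, f0),
               tolerance = 1e-12)
})

test_that("per-beat dF/F0 amplitude is flat across beats despite bleaching", {
  mm <- small_movie()
  seg <- segmentMovie(mm$movie)
  raw <- regionTraces(seg)[, 1]
  bl <- alsBaseline(raw)
  df <- normalizeDFF0(raw, bl)
  # amplitude of each of the two subsequent beats relative to the first
  amps <- vapply(c(0, 1000), function(s) {
    seg_idx <- (s + 1):(s + 900)
    max(df[seg_idx]) - median(df[(s + 900):(s + 980)])
  }, numeric(1))
  expect_lt(abs(amps[2] - amps[1]) / amps[1], 0.03)
})

test_that("the bilateral filter matches a direct double-loop oracle", {
  set.seed(4)
  x <- cumsum(rnorm(80))
  window <- 9; sigma_s <- 2.5; sigma_r <- 1.2
  out <- bilateralFilter1D(x, window, sigma_s, sigma_r)
  # oracle: direct sums with mirrored edges
  half <- window %/% 2
  mirror <- function(i, n) {
    p <- 2 * n - 2
    i <- ((i %% p) + p) %% p
    if (i < n) i + 1 else p - i + 1
  }
  oracle <- numeric(80)
  for (i in seq_len(80)) {
    num <- den <- 0
    for (k in -half:half) {
      xj <- x[mirror(i - 1 + k, 80)]
      w <- exp(-0.5 * k^2 / sigma_s^2) *
        exp(-0.5 * (xj - x[i])^2 / sigma_r^2)
      num <- num + w * xj; den <- den + w
    }
    oracle[i] <- num / den
  }
  expect_equal(out, oracle, tolerance = 1e-12)

  # convex combination: output bounded by the window values
  expect_true(all(out >= min(x) - 1e-12 & out <= max(x) + 1e-12))
})

test_that("bilateral filtering degenerates and preserves edges as designed", {
  expect_equal(bilateralFilter1D(rep(2, 50), 15, 3, 1), rep(2, 50))
  # sigma_r -> Inf reduces to plain Gaussian smoothing
  set.seed(6)
  x <- rnorm(60)
  bi <- bilateralFilter1D(x, 15, sigmaS = 15 / 4, sigmaR = 1e12)
  ga <- gaussianFilter1D(x, sigma = 15 / 4, window = 15)
  expect_equal(bi, ga, tolerance = 1e-9)

  # ideal step: bilateral keeps >= 90% of the step slope, Gaussian < 50%
  h <- 1
  x <- c(rep(0, 40), rep(h, 40))
  bi <- bilateralFilter1D(x, 15, sigmaS = 15 / 4, sigmaR = h / 5)
  ga <- gaussianFilter1D(x, sigma = 15 / 4, window = 15)
  slope <- function(v) max(diff(v))
  expect_gte(slope(bi), 0.9 * h)
  expect_lt(slope(ga), 0.5 * h)
})

test_that("gaussian filtering matches its kernel and reduces noise variance", {
  x <- c(rep(0, 20), 1, rep(0, 20))
  out <- gaussianFilter1D(x, sigma = 2, window = 9)
  k <- exp(-0.5 * ((-4:4) / 2)^2); k <- k / sum(k)
  expect_equal(out[17:25], k, tolerance = 1e-12)
  expect_equal(gaussianFilter1D(rep(3, 30), 2, 9), rep(3, 30))
  set.seed(9)
  x <- rnorm(5000)
  expect_lt(var(gaussianFilter1D(x, 4, 25)), var(x))
})
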