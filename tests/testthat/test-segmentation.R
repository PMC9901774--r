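# Segmentation: FFT-amplitude image vs a brute-force DFT oracle, histogram
# entropy, both thresholding criteria vs exhaustive-search oracles,
# connected-component labeling, and trace averaging.

test_that("fftMaxImage matches trivial spectra and the pacing-band contract", {
  # constant pixel traces carry no spectral power after mean removal
  arr <- array(5, dim = c(3, 3, 64))
  mv <- OpticalMovie(arr, frameRate = 64, pacingCL = 8000)
  fm <- fftMaxImage(mv, band = c(2, 10), detrend = FALSE)
  expect_equal(max(abs(fm$values)), 0)

  # single tone of amplitude A at an exact DFT bin: un-normalized DFT gives
  # A * N / 2
  N <- 128; fr <- 128; f <- 8; A <- 3
  tt <- (0:(N - 1)) / fr
  arr <- array(rep(A * sin(2 * pi * f * tt), each = 4), dim = c(2, 2, N))
  mv <- OpticalMovie(arr, frameRate = fr)
  fm <- fftMaxImage(mv, band = c(4, 12), detrend = FALSE)
  expect_equal(as.vector(fm$values), rep(A * N / 2, 4), tolerance = 1e-9)

  # empty band errors and names the frequency resolution
  expect_error(fftMaxImage(mv, band = c(0.2, 0.4)), "resolution")
  expect_error(fftMaxImage(mv, band = c(10, 100)), "frameRate/2")
})

test_that("fftMaxImage equals a direct O(N^2) DFT oracle per pixel", {
  set.seed(21)
  N <- 64
  arr <- array(rnorm(8 * 8 * N), dim = c(8, 8, N))
  mv <- OpticalMovie(arr, frameRate = N)
  band <- c(3, 17)
  fm <- fftMaxImage(mv, band = band, detrend = FALSE)
  freq <- (0:(N - 1)) * N / N
  bins <- which(freq >= band[1] & freq <= band[2] & (0:(N - 1)) >= 1)
  oracle <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8) {
    x <- arr[r, c, ] - mean(arr[r, c, ])
    best <- 0
    for (k in bins) {
      re <- sum(x * cos(-2 * pi * (k - 1) * (0:(N - 1)) / N))
      im <- sum(x * sin(-2 * pi * (k - 1) * (0:(N - 1)) / N))
      best <- max(best, sqrt(re^2 + im^2))
    }
    oracle[r, c] <- best
  }
  expect_equal(fm$values, oracle, tolerance = 1e-9)
})

test_that("fftMaxImage is invariant to a constant offset on every frame", {
  mm <- small_movie()
  fm1 <- fftMaxImage(mm$movie)
  shifted <- mm$movie
  shifted@data <- shifted@data + 17.3
  fm2 <- fftMaxImage(shifted)
  expect_equal(fm1$values, fm2$values, tolerance = 1e-9)
})

test_that("histogram entropy matches hand-computed cases", {
  expect_equal(histogramEntropy(matrix(3, 5, 5)), 0)
  # exactly uniform over 256 bins
  x <- matrix(rep((0:255) / 255, 4), 32, 32)
  expect_equal(histogramEntropy(x, nbins = 256), 8)
  # two equal-mass bins
  expect_equal(histogramEntropy(rep(c(0, 1), 50), nbins = 2), 1)
})

test_that("the FFT-amplitude image has better contrast than raw fluorescence", {
  # the motivation for segmenting on the spectral image: its histogram
  # concentrates background into few bins, lowering entropy
  mm <- small_movie()
  fm <- fftMaxImage(mm$movie)
  h_fft <- histogramEntropy(fm$values)
  h_raw <- histogramEntropy(mm$movie@data[, , 10])
  expect_lt(h_fft, h_raw)
})

test_that("both threshold criteria equal exhaustive-search oracles", {
  # trivial bimodal case: threshold strictly between the two spikes
  x <- c(rep(10, 40), rep(200, 60))
  thr <- otsuThreshold(x, nbins = 16)
  expect_gt(thr, 10); expect_lt(thr, 200)
  thr2 <- minCrossEntropyThreshold(x, nbins = 16)
  expect_gt(thr2, 10); expect_lt(thr2, 200)

  # randomized sweep of small 16-level images
  set.seed(5)
  for (i in 1:150) {
    n <- sample(6:64, 1)
    x <- sample(1:16, n, replace = TRUE) +
      if (i %% 2 == 0) 0 else 0.5 * rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) next
    or <- .oracle_thresholds(x, 16)
    expect_equal(otsuThreshold(x, nbins = 16), or$otsu, tolerance = 1e-12)
    expect_equal(minCrossEntropyThreshold(x, nbins = 16), or$li,
                 tolerance = 1e-12)
  }

  # exhaustive enumeration of all 4-sample images over 4 levels
  grid <- expand.grid(1:4, 1:4, 1:4, 1:4)
  for (r in seq_len(nrow(grid))) {
    x <- as.numeric(grid[r, ])
    if (length(unique(x)) < 2) next
    or <- .oracle_thresholds(x, 4)
    expect_equal(otsuThreshold(x, nbins = 4), or$otsu, tolerance = 1e-12)
    expect_equal(minCrossEntropyThreshold(x, nbins = 4), or$li,
                 tolerance = 1e-12)
  }
})

test_that("constant images cannot be thresholded", {
  expect_error(otsuThreshold(matrix(1, 4, 4)), "constant")
  expect_error(minCrossEntropyThreshold(matrix(1, 4, 4)), "constant")
})

test_that("thresholding the spectral image separates tissue from background", {
  mm <- small_movie()
  fm <- fftMaxImage(mm$movie)
  for (method in c("otsu", "li")) {
    thr <- if (method == "otsu") otsuThreshold(fm$values)
           else minCrossEntropyThreshold(fm$values)
    sel <- fm$values > thr
    expect_gt(mean(sel[mm$labels > 0]), 0.95)   # tissue pixels above
    expect_gt(mean(!sel[mm$labels == 0]), 0.95) # background below
  }
})

test_that("cross entropy selects at least as much tissue area as Otsu on dim edges", {
  # tissues whose rims carry reduced amplitude: the conservative Otsu
  # threshold clips rim pixels; minimum cross entropy keeps them
  set.seed(3)
  spec <- MovieSpec(height = 50, width = 50, nFrames = 1500, frameRate = 1000,
                    gridRows = 2, gridCols = 2, tissueRadius = 8,
                    pacingCL = 500, bleachTau = Inf, driftPoly = 0,
                    backgroundLevel = 0.3, noiseSd = 0.04, seed = 13)
  ws <- WaveformSpec(takeoffTime = 5, riseTime = 4, apd50 = 120, apd80 = 150,
                     apdMxr = 180, restingLevel = 0.5)
  mm <- makeMovie(spec, ws)
  # taper the AP amplitude toward each disk edge
  arr <- mm$movie@data
  for (i in 1:4) {
    idx <- which(mm$labels == i, arr.ind = TRUE)
    cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
    d <- sqrt((idx[, 1] - cr)^2 + (idx[, 2] - cc)^2)
    taper <- pmax(0.15, 1 - (d / 9)^2)
    for (p in seq_len(nrow(idx))) {
      tr <- arr[idx[p, 1], idx[p, 2], ]
      arr[idx[p, 1], idx[p, 2], ] <- median(tr) + (tr - median(tr)) * taper[p]
    }
  }
  mv <- OpticalMovie(arr, 1000, spec@stimTimes, spec@pacingCL)
  fm <- fftMaxImage(mv)
  a_otsu <- sum(fm$values > otsuThreshold(fm$values))
  a_li <- sum(fm$values > minCrossEntropyThreshold(fm$values))
  expect_gte(a_li, a_otsu)
})

test_that("region labeling filters by area and orders labels in raster order", {
  mask <- matrix(FALSE, 12, 12)
  mask[2:4, 2:4] <- TRUE    # block of 9
  mask[8:10, 7:9] <- TRUE   # block of 9
  rs <- labelRegions(mask, minArea = 4)
  expect_equal(nrow(regionTable(rs)), 2)
  expect_equal(regionTable(rs)$area, c(9, 9))
  # raster order: upper block first
  expect_lt(regionTable(rs)$centroid_row[1], regionTable(rs)$centroid_row[2])
  rs2 <- labelRegions(mask, minArea = 10)
  expect_equal(nrow(regionTable(rs2)), 0)

  # diagonal touch: joined under 8-connectivity, split under 4
  m2 <- matrix(FALSE, 4, 4)
  m2[1:2, 1:2] <- TRUE; m2[3:4, 3:4] <- TRUE
  expect_equal(nrow(regionTable(labelRegions(m2, 1, connectivity = 8))), 1)
  expect_equal(nrow(regionTable(labelRegions(m2, 1, connectivity = 4))), 2)
})

test_that("region traces average pixels and suppress noise like 1/sqrt(n)", {
  arr <- array(0, dim = c(4, 4, 50))
  base <- sin(seq_len(50) / 5)
  arr[1, 1, ] <- base
  arr[2, 1, ] <- 3 * base
  mv <- OpticalMovie(arr, frameRate = 100)
  mask1 <- matrix(FALSE, 4, 4); mask1[1, 1] <- TRUE
  expect_equal(regionTrace(mv, mask1), base)
  mask2 <- matrix(FALSE, 4, 4); mask2[1:2, 1] <- TRUE
  expect_equal(regionTrace(mv, mask2), 2 * base)
  expect_error(regionTrace(mv, matrix(FALSE, 4, 4)), "empty")

  # Monte-Carlo: averaging n i.i.d.-noise pixels reduces the residual SD to
  # about sigma/sqrt(n)
  set.seed(8)
  n_px <- 36; sigma <- 0.5
  arr <- array(rnorm(6 * 6 * 4000, sd = sigma), dim = c(6, 6, 4000))
  mv <- OpticalMovie(arr, frameRate = 1000)
  tr <- regionTrace(mv, matrix(TRUE, 6, 6))
  expect_lt(abs(sd(tr) - sigma / sqrt(n_px)) / (sigma / sqrt(n_px)), 0.2)
})

test_that("a 4x4 grid is fully recovered with high overlap", {
  mm <- grid16_movie()
  seg <- segmentMovie(mm$movie)
  expect_equal(nrow(regionTable(seg)), 16)
  jac <- vapply(1:16, function(i) jaccard(labelImage(seg), mm$labels, i),
                numeric(1))
  expect_gte(sum(jac >= 0.8), 15)
  expect_true(all(jac > 0.5))
})
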