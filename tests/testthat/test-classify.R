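# Feature construction, PCA, and the block classifier.

test_that("percent-change features follow their definition", {
  ref <- data.frame(cell = 1:4, rise_ms = c(4, 5, 4.5, 5.5),
                    apd50_ms = c(230, 240, 220, 250),
                    apd80_ms = c(270, 280, 260, 290))
  expect_equal(
    as.numeric(as.matrix(percentChangeFeatures(ref, ref)[, 1:3])),
    rep(0, 12))

  # the Table-1-style arithmetic: 230 -> 178 is -22.6%
  blk <- ref
  blk$apd50_ms <- ref$apd50_ms * 178 / 230
  pc <- percentChangeFeatures(blk, ref)
  expect_equal(pc$apd50_ms, rep(100 * (178 - 230) / 230, 4),
               tolerance = 1e-9)

  # unpaired mode contrasts against the reference mean
  blk2 <- data.frame(rise_ms = 6, apd50_ms = 235, apd80_ms = 275)
  pc2 <- percentChangeFeatures(blk2, ref, pairing = "unpaired")
  expect_equal(pc2$apd50_ms, 100 * (235 - 235) / 235, tolerance = 1e-9)

  # rows with undefined metrics are dropped and counted
  blk3 <- ref; blk3$apd50_ms[2] <- NA
  pc3 <- percentChangeFeatures(blk3, ref)
  expect_equal(nrow(pc3), 3)
  expect_equal(attr(pc3, "n_dropped"), 1)
})

test_that("PCA matches a direct correlation-eigendecomposition oracle", {
  set.seed(40)
  x <- matrix(rnorm(40 * 5), 40, 5) %*% matrix(rnorm(25), 5, 5)
  colnames(x) <- paste0("f", 1:5)
  p <- fitPCA(x)
  ev <- eigen(cor(x))
  expect_equal(p$explained_variance_ratio, ev$values / sum(ev$values),
               tolerance = 1e-9)
  for (j in 1:5) {
    a <- p$loadings[, j]; b <- ev$vectors[, j]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-9)  # equal up to sign
    # sign convention: largest-magnitude loading positive
    expect_gt(a[which.max(abs(a))], 0)
  }
  expect_equal(sum(p$explained_variance_ratio), 1, tolerance = 1e-12)

  # collinear data: one axis explains everything
  z <- cbind(a = 1:30, b = 2 * (1:30) + 3)
  expect_equal(fitPCA(z)$explained_variance_ratio[1], 1, tolerance = 1e-9)

  # invariant to feature order
  p2 <- fitPCA(x[, c(3, 1, 5, 2, 4)])
  expect_equal(sort(p2$explained_variance_ratio),
               sort(p$explained_variance_ratio), tolerance = 1e-9)

  # zero-variance feature dropped with a warning
  expect_warning(fitPCA(cbind(x, const = 1)), "zero-variance")
})

test_that("the classifier protocol behaves on analytic datasets", {
  set.seed(41)
  # widely separated blobs: perfect accuracy
  n <- 60
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2, mean = 10), n, 2))
  colnames(x) <- c("rise_ms", "apd50_ms")
  y <- rep(c("a", "b"), each = n)
  rep_out <- trainEvalLogreg(as.data.frame(x), y, nRepeats = 3, seed = 2)
  expect_equal(unname(rep_out$overall["mean"]), 1)

  # known Bayes error of 10%: test accuracy within 3 points of 90%
  n <- 1500
  d <- 2 * qnorm(0.9)
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             cbind(rnorm(n, mean = d), rnorm(n)))
  colnames(x) <- c("rise_ms", "apd50_ms")
  y <- rep(c("a", "b"), each = n)
  rep_out <- trainEvalLogreg(as.data.frame(x), y, nRepeats = 3, seed = 3)
  expect_lt(abs(rep_out$overall["mean"] - 0.90), 0.03)

  # affine rescaling of a feature is absorbed by standardization
  xs <- x; xs[, 2] <- 1000 * xs[, 2] + 55
  rep_scaled <- trainEvalLogreg(as.data.frame(xs), y, nRepeats = 3, seed = 3)
  expect_equal(unname(rep_scaled$overall["mean"]),
               unname(rep_out$overall["mean"]), tolerance = 5e-3)

  # classes below 5 samples are rejected
  expect_error(trainEvalLogreg(as.data.frame(x[1:8, ]),
                               c(rep("a", 6), "b", "b")), "at least 5")
})

test_that("stratified splitting preserves class proportions within 1 sample", {
  y <- factor(rep(c("a", "b", "c"), times = c(40, 25, 10)))
  withSeed <- getFromNamespace("withSeed", "cardiomap")
  idx <- withSeed(7, cardiomap:::.stratified_idx(y, 0.8))
  tab <- table(y[idx])
  expect_lte(abs(tab[["a"]] - 32), 1)
  expect_lte(abs(tab[["b"]] - 20), 1)
  expect_lte(abs(tab[["c"]] - 8), 1)
  # folds cover every sample exactly once
  fold <- withSeed(8, cardiomap:::.stratified_folds(y, 5))
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), length(y))
})
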