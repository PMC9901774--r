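# Segmentation of individual microtissues from a fluorescence movie:
# a per-pixel FFT-amplitude map within the pacing band highlights pixels
# carrying AP signal; histogram thresholding (minimum cross entropy by
# default, Otsu for comparison) and connected-component labeling then
# identify the tissues, and pixel traces are averaged per region.

#' Per-pixel maximum Fourier amplitude within the pacing band
#'
#' Each pixel trace is linearly detrended (removing the mean and any linear
#' bleaching trend, so constant offsets never contribute) and transformed
#' with an un-normalized DFT; the pixel value of the returned image is the
#' maximum DFT magnitude over the frequency bins falling inside \code{band}.
#' A pure tone \code{A*sin(2*pi*f*t)} with f inside the band maps to
#' \code{A*N/2}.
#'
#' @param movie an \linkS4class{OpticalMovie}.
#' @param band numeric length-2 frequency interval in Hz. Default
#'   \code{c(0.5, 1.5) * 1000/pacingCL}, a proportional band around the
#'   pacing frequency that tolerates drift in spontaneous rate.
#' @param detrend linearly detrend pixel traces before the DFT (default
#'   TRUE; reduces leakage from bleaching into the pacing band).
#' @return list with \code{values} (height x width matrix of maximal
#'   spectral amplitude) and \code{band}.
#' @export
fftMaxImage <- function(movie, band = NULL, detrend = TRUE) {
  stopifnot(is(movie, "OpticalMovie"))
  fr <- movie@frameRate
  if (is.null(band)) {
    if (is.na(movie@pacingCL))
      stop("band must be given when the movie has no pacing cycle length")
    fpace <- 1000 / movie@pacingCL
    band <- c(0.5, 1.5) * fpace
  }
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] <= 0 || band[2] >= fr / 2)
    stop("band must lie within (0, frameRate/2)")
  d <- dim(movie@data)
  nf <- d[3]
  freq <- (seq_len(nf) - 1) * fr / nf
  bins <- which(freq >= band[1] & freq <= band[2] & seq_len(nf) > 1)
  if (length(bins) == 0)
    stop(sprintf(paste0("no DFT bins inside band [%.3g, %.3g] Hz: frequency ",
                        "resolution is %.3g Hz (frameRate/nFrames); record ",
                        "longer or widen the band"),
                 band[1], band[2], fr / nf))

  npix <- d[1] * d[2]
  y <- matrix(movie@data, nrow = npix, ncol = nf)
  out <- numeric(npix)
  tt <- seq_len(nf)
  # process pixels in blocks to bound the complex work array
  block <- max(1L, floor(2e6 / nf))
  for (start in seq(1L, npix, by = block)) {
    idx <- start:min(npix, start + block - 1L)
    yb <- t(y[idx, , drop = FALSE])  # nf x nblock
    if (detrend) {
      fit <- lm.fit(cbind(1, tt), yb)
      yb <- yb - cbind(1, tt) %*% fit$coefficients
    } else {
      yb <- sweep(yb, 2, colMeans(yb))
    }
    sp <- Mod(mvfft(yb))
    out[idx] <- apply(sp[bins, , drop = FALSE], 2, max)
  }
  list(values = matrix(out, d[1], d[2]), band = band)
}

#' Shannon entropy of an image's intensity histogram
#'
#' @param image numeric matrix (or the list returned by
#'   \code{\link{fftMaxImage}}).
#' @param nbins number of histogram bins (default 256).
#' @return entropy in bits.
#' @export
histogramEntropy <- function(image, nbins = 256) {
  x <- if (is.list(image)) image$values else image
  x <- as.numeric(x)
  stopifnot(length(x) > 0)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  cuts <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# histogram (counts + bin centers + upper edges) shared by both thresholds
.image_hist <- function(x, nbins) {
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant image: no threshold exists")
  cuts <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  list(counts = counts, centers = (cuts[-1] + cuts[-(nbins + 1)]) / 2,
       edges = cuts)
}

#' Otsu's threshold
#'
#' Histogram threshold minimizing the weighted within-class intensity
#' variance (equivalently maximizing between-class variance). Ties are
#' broken toward the lowest qualifying threshold.
#'
#' @param image numeric matrix or vector (or an \code{fftMaxImage} result).
#' @param nbins number of histogram bins (default 256).
#' @return threshold value (pixels > threshold are foreground).
#' @export
otsuThreshold <- function(image, nbins = 256) {
  x <- as.numeric(if (is.list(image)) image$values else image)
  h <- .image_hist(x, nbins)
  cnt <- h$counts; g <- h$centers
  n <- sum(cnt)
  w1 <- cumsum(cnt)
  m1 <- cumsum(cnt * g)
  mT <- m1[length(m1)]
  # between-class variance for split after bin t (candidates with both
  # classes nonempty)
  valid <- which(w1 > 0 & w1 < n)
  mu1 <- m1[valid] / w1[valid]
  mu2 <- (mT - m1[valid]) / (n - w1[valid])
  bcv <- w1[valid] * (n - w1[valid]) * (mu1 - mu2)^2
  best <- valid[which.max(bcv)]  # which.max takes the first (lowest) maximum
  h$edges[best + 1]
}

#' Minimum cross entropy (Li) threshold
#'
#' Histogram threshold minimizing the Li-Lee cross entropy between the image
#' and its two-level class-mean reconstruction,
#' \code{eta(t) = -sum_{g<=t} g h(g) log(mu_low) - sum_{g>t} g h(g) log(mu_high)}.
#' Intensities must be positive; images whose minimum is <= 0 are shifted up
#' before thresholding and the returned threshold is shifted back.
#'
#' @inheritParams otsuThreshold
#' @return threshold value (pixels > threshold are foreground).
#' @export
minCrossEntropyThreshold <- function(image, nbins = 256) {
  x <- as.numeric(if (is.list(image)) image$values else image)
  shift <- 0
  if (min(x) <= 0) {
    shift <- diff(range(x)) * 1e-3 - min(x)
    if (shift <= 0) shift <- 1 - min(x)
    x <- x + shift
  }
  h <- .image_hist(x, nbins)
  cnt <- h$counts; g <- h$centers
  n <- sum(cnt)
  w1 <- cumsum(cnt)
  m1 <- cumsum(cnt * g)
  mT <- m1[length(m1)]
  valid <- which(w1 > 0 & w1 < n)
  mu1 <- m1[valid] / w1[valid]
  mu2 <- (mT - m1[valid]) / (n - w1[valid])
  eta <- -m1[valid] * log(mu1) - (mT - m1[valid]) * log(mu2)
  best <- valid[which.min(eta)]  # first (lowest) minimum on ties
  h$edges[best + 1] - shift
}

#' Label connected foreground regions
#'
#' Connected-component labeling of a binary mask with a minimum-area filter.
#' Surviving regions are relabeled 1..k in raster order of their centroids
#' (by centroid row, then column).
#'
#' @param mask logical matrix.
#' @param minArea minimum region area in pixels (default 20).
#' @param connectivity 4 or 8 (default 8).
#' @return A \linkS4class{TissueRegionSet} (without traces).
#' @export
labelRegions <- function(mask, minArea = 20, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  lab <- .label_cc_cpp(mask, as.integer(connectivity))
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  keep <- list()
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < minArea) {
      lab[lab == id] <- 0L
      next
    }
    keep[[length(keep) + 1]] <- data.frame(
      old = id, area = nrow(idx),
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]))
  }
  if (length(keep) == 0) {
    return(new("TissueRegionSet", labelImage = matrix(0L, nrow(mask), ncol(mask)),
               regions = data.frame(label = integer(0), area = integer(0),
                                    centroid_row = numeric(0),
                                    centroid_col = numeric(0)),
               traces = matrix(numeric(0), 0, 0), method = "manual",
               threshold = NA_real_))
  }
  tab <- do.call(rbind, keep)
  ord <- order(tab$centroid_row, tab$centroid_col)
  tab <- tab[ord, , drop = FALSE]
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(tab))) out[lab == tab$old[i]] <- i
  regions <- data.frame(label = seq_len(nrow(tab)), area = tab$area,
                        centroid_row = tab$centroid_row,
                        centroid_col = tab$centroid_col)
  new("TissueRegionSet", labelImage = out, regions = regions,
      traces = matrix(numeric(0), 0, 0), method = "manual",
      threshold = NA_real_)
}

#' Average the pixel traces of one region
#'
#' @param movie an \linkS4class{OpticalMovie}.
#' @param region either a logical matrix, or a \linkS4class{TissueRegionSet}
#'   together with \code{label}.
#' @param label region label when \code{region} is a TissueRegionSet.
#' @return numeric trace: the frame-wise arithmetic mean over region pixels.
#' @export
regionTrace <- function(movie, region, label = NULL) {
  stopifnot(is(movie, "OpticalMovie"))
  mask <- if (is(region, "TissueRegionSet")) {
    stopifnot(!is.null(label))
    region@labelImage == label
  } else region
  idx <- which(mask)
  if (length(idx) == 0) stop("empty region")
  d <- dim(movie@data)
  y <- matrix(movie@data, nrow = d[1] * d[2], ncol = d[3])
  colMeans(y[idx, , drop = FALSE])
}

#' Segment a movie into microtissue regions with averaged traces
#'
#' Full segmentation stage: FFT-amplitude image within the pacing band,
#' histogram threshold (minimum cross entropy by default; Otsu available
#' for comparison), connected-component labeling
#' with an area filter, and per-region trace averaging.
#'
#' @param movie an \linkS4class{OpticalMovie}.
#' @param method "li" (minimum cross entropy, default) or "otsu".
#' @param band pacing band in Hz passed to \code{\link{fftMaxImage}}.
#' @param minArea,connectivity see \code{\link{labelRegions}}.
#' @param nbins histogram bins for thresholding.
#' @return A \linkS4class{TissueRegionSet} with traces.
#' @export
segmentMovie <- function(movie, method = c("li", "otsu"), band = NULL,
                         minArea = 20, connectivity = 8, nbins = 256) {
  method <- match.arg(method)
  fm <- fftMaxImage(movie, band = band)
  thr <- if (method == "li") minCrossEntropyThreshold(fm$values, nbins)
         else otsuThreshold(fm$values, nbins)
  rs <- labelRegions(fm$values > thr, minArea = minArea,
                     connectivity = connectivity)
  k <- nrow(rs@regions)
  d <- dim(movie@data)
  traces <- matrix(numeric(0), 0, 0)
  if (k > 0) {
    y <- matrix(movie@data, nrow = d[1] * d[2], ncol = d[3])
    traces <- matrix(0, d[3], k)
    for (i in seq_len(k))
      traces[, i] <- colMeans(y[which(rs@labelImage == i), , drop = FALSE])
    colnames(traces) <- paste0("region_", seq_len(k))
  }
  new("TissueRegionSet", labelImage = rs@labelImage, regions = rs@regions,
      traces = traces, method = method, threshold = thr)
}
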