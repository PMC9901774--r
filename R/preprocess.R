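# Baseline-drift removal, dF/F0 normalization, and edge-preserving
# denoising of per-tissue fluorescence traces.

# reflect-pad a vector by `half` samples on each side
.reflect_pad <- function(x, half) {
  n <- length(x)
  stopifnot(half < n)
  c(x[(half + 1):2], x, x[(n - 1):(n - half)])
}

#' Asymmetric least squares polynomial baseline
#'
#' Iteratively reweighted polynomial fit of the slow baseline under an AP
#' train. The trace is first decimated to \code{nDownsample} points (only the
#' slow baseline matters), then fitted by weighted polynomial least squares:
#' the first iteration uses unit weights, and in every later iteration points
#' lying above the current fit are down-weighted by the asymmetry factor
#' \code{p} while points at or below keep weight 1, pulling the fit onto the
#' diastolic baseline. After \code{nIter} iterations the polynomial is
#' evaluated on the full-resolution grid.
#'
#' Action potentials must deflect upward (positive polarity); flip the sign
#' of inverted traces first.
#'
#' @param x numeric trace (raw fluorescence) or an \linkS4class{APTrace}.
#' @param polyOrder polynomial order (default 3).
#' @param p asymmetry weight for points above the fit (default 0.001).
#' @param nIter number of fit iterations (default 5).
#' @param nDownsample decimation length (default 512; must exceed
#'   \code{polyOrder}).
#' @return numeric baseline, same length as the input trace.
#' @export
alsBaseline <- function(x, polyOrder = 3, p = 0.001, nIter = 5,
                        nDownsample = 512) {
  if (is(x, "APTrace")) x <- x@values
  n <- length(x)
  stopifnot(polyOrder >= 1, p > 0, p <= 1, nIter >= 1,
            nDownsample >= polyOrder + 1)
  idx <- if (n > nDownsample)
    unique(round(seq(1, n, length.out = nDownsample))) else seq_len(n)
  y <- x[idx]
  tt <- 2 * (idx - 1) / (n - 1) - 1  # scale time to [-1, 1] for conditioning
  X <- outer(tt, 0:polyOrder, `^`)
  w <- rep(1, length(y))
  for (i in seq_len(nIter)) {
    fit <- lm.wfit(X, y, w)
    yhat <- as.numeric(X %*% fit$coefficients)
    w <- ifelse(y > yhat, p, 1)
  }
  tfull <- 2 * (seq_len(n) - 1) / (n - 1) - 1
  as.numeric(outer(tfull, 0:polyOrder, `^`) %*% fit$coefficients)
}

#' Normalize fluorescence to dF/F0
#'
#' \code{(F - F0) / F0} per timepoint, with F0 the fitted baseline. The
#' result is invariant to a common positive gain on F and F0, which removes
#' bleaching and illumination differences between beats and tissues.
#'
#' @param x numeric trace or \linkS4class{APTrace} (raw fluorescence).
#' @param baseline fitted baseline F0, same length (e.g. from
#'   \code{\link{alsBaseline}}).
#' @return numeric dF/F0 trace (or an \linkS4class{APTrace} when the input
#'   was one).
#' @export
normalizeDFF0 <- function(x, baseline) {
  vals <- if (is(x, "APTrace")) x@values else x
  stopifnot(length(vals) == length(baseline))
  if (any(baseline <= 0))
    stop(paste0("baseline is <= 0 at some timepoints: subtract the camera ",
                "dark offset before normalization so F0 reflects true ",
                "fluorescence"))
  out <- (vals - baseline) / baseline
  if (is(x, "APTrace")) {
    x@values <- out
    x
  } else out
}

#' Edge-preserving 1-D bilateral filter
#'
#' Gaussian smoothing with an additional intensity-range kernel: neighbors
#' whose value differs from the center by much more than \code{sigmaR}
#' barely contribute, so the sharp AP upstroke survives smoothing that
#' would be blurred away by a plain Gaussian of the same width. With
#' \code{sigmaR = Inf} (or very large) the filter reduces to Gaussian
#' smoothing. Edges are reflect-padded; the output at every sample is a
#' convex combination of the window values.
#'
#' @param x numeric trace or \linkS4class{APTrace}.
#' @param window odd window length in samples (default 15).
#' @param sigmaS spatial Gaussian width in samples (default window/4).
#' @param sigmaR range Gaussian width in intensity units; default 30\% of a
#'   robust amplitude estimate (0.5\%..99.5\% quantile range).
#' @return filtered trace, same class as the input.
#' @export
bilateralFilter1D <- function(x, window = 15, sigmaS = window / 4,
                              sigmaR = NULL) {
  vals <- if (is(x, "APTrace")) x@values else x
  stopifnot(window %% 2 == 1, window >= 3, window <= length(vals), sigmaS > 0)
  if (is.null(sigmaR)) {
    amp <- diff(quantile(vals, c(0.005, 0.995), names = FALSE))
    sigmaR <- 0.3 * amp
    if (sigmaR <= 0) sigmaR <- 1
  }
  stopifnot(sigmaR > 0)
  out <- .bilateral1d_cpp(as.numeric(vals), as.integer(window),
                          sigmaS, sigmaR)
  if (is(x, "APTrace")) { x@values <- out; x } else out
}

#' Truncated Gaussian smoothing filter
#'
#' Plain Gaussian convolution with reflect padding; the comparison baseline
#' for the bilateral filter.
#'
#' @param x numeric trace or \linkS4class{APTrace}.
#' @param sigma Gaussian width in samples.
#' @param window odd kernel length; default \code{2*ceiling(3*sigma) + 1}.
#' @return filtered trace, same class as the input.
#' @export
gaussianFilter1D <- function(x, sigma, window = NULL) {
  vals <- if (is(x, "APTrace")) x@values else x
  if (is.null(window)) window <- 2 * ceiling(3 * sigma) + 1
  stopifnot(window %% 2 == 1, window >= 1, sigma > 0)
  half <- window %/% 2
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  if (half == 0) return(x)
  padded <- .reflect_pad(vals, half)
  out <- as.numeric(stats::filter(padded, rev(k), sides = 2))
  out <- out[(half + 1):(half + length(vals))]
  if (is(x, "APTrace")) { x@values <- out; x } else out
}

#' Preprocess a raw fluorescence trace
#'
#' Convenience wrapper chaining the three preprocessing steps: asymmetric
#' least squares baseline fit, dF/F0 normalization, and bilateral filtering.
#'
#' @param trace an \linkS4class{APTrace} with raw fluorescence values, or a
#'   numeric vector together with \code{samplePeriod}.
#' @param samplePeriod ms per sample (when \code{trace} is numeric).
#' @param stimTimes stimulus times, ms (when \code{trace} is numeric).
#' @param offset camera dark offset subtracted before normalization
#'   (default 0).
#' @param polyOrder,p,nIter,nDownsample see \code{\link{alsBaseline}}.
#' @param window,sigmaS,sigmaR see \code{\link{bilateralFilter1D}};
#'   \code{window = 0} skips filtering.
#' @return an \linkS4class{APTrace} holding the filtered dF/F0 trace.
#' @export
preprocessTrace <- function(trace, samplePeriod = NULL, stimTimes = numeric(0),
                            offset = 0, polyOrder = 3, p = 0.001, nIter = 5,
                            nDownsample = 512, window = 15,
                            sigmaS = window / 4, sigmaR = NULL) {
  if (!is(trace, "APTrace")) {
    stopifnot(!is.null(samplePeriod))
    trace <- APTrace(trace, samplePeriod, stimTimes)
  }
  vals <- trace@values - offset
  bl <- alsBaseline(vals, polyOrder = polyOrder, p = p, nIter = nIter,
                    nDownsample = nDownsample)
  df <- normalizeDFF0(vals, bl)
  if (window >= 3)
    df <- bilateralFilter1D(df, window = window, sigmaS = sigmaS,
                            sigmaR = sigmaR)
  trace@values <- df
  trace
}
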