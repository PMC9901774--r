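# Synthetic fluorescence movies and AP traces with closed-form ground truth.
# The waveform family is deliberately simple: a linear upstroke, a power-law
# plateau that crosses 50% repolarization exactly at apd50, linear segments
# through the 80% crossing, and a slope discontinuity at apdMxr where a slow
# exponential tail begins, so every downstream metric is analytically known.

# repolarization fraction (1 at peak, 0 at rest) as a function of time from
# takeoff; vectorized in tau
.waveform_fraction <- function(spec, tau) {
  r <- spec@riseTime; a50 <- spec@apd50; a80 <- spec@apd80
  amxr <- spec@apdMxr; k <- spec@plateauShape; fm <- spec@mxrLevel
  f <- numeric(length(tau))
  i <- tau >= 0 & tau < r
  f[i] <- tau[i] / r
  i <- tau >= r & tau < a50
  f[i] <- 1 - 0.5 * ((tau[i] - r) / (a50 - r))^k
  i <- tau >= a50 & tau < a80
  f[i] <- 0.5 - 0.3 * (tau[i] - a50) / (a80 - a50)
  i <- tau >= a80 & tau < amxr
  f[i] <- 0.2 - (0.2 - fm) * (tau[i] - a80) / (amxr - a80)
  i <- tau >= amxr
  f[i] <- fm * exp(-(tau[i] - amxr) / spec@tailTau)
  f
}

#' Sample a parametric surrogate action potential
#'
#' Evaluates the waveform described by a \linkS4class{WaveformSpec} on a time
#' grid. The waveform rests at \code{restingLevel} before takeoff, rises
#' linearly to \code{restingLevel + amplitude} over \code{riseTime}, then
#' repolarizes monotonically, crossing 50\% and 80\% of the amplitude exactly
#' at \code{apd50} and \code{apd80} after takeoff; at \code{apdMxr} the decay
#' slope drops discontinuously into a slow exponential tail, placing the
#' late-repolarization curvature maximum exactly there.
#'
#' @param spec a \linkS4class{WaveformSpec}.
#' @param t time grid in ms (uniform).
#' @return numeric vector of fluorescence values, same length as \code{t}.
#' @seealso \code{\link{waveformGroundTruth}}
#' @export
makeWaveform <- function(spec, t) {
  stopifnot(is(spec, "WaveformSpec"))
  validObject(spec)
  spec@restingLevel + spec@amplitude *
    .waveform_fraction(spec, t - spec@takeoffTime)
}

#' Ground-truth metrics of a surrogate waveform
#'
#' Closed-form values of the metrics the analysis pipeline should recover
#' from a \code{\link{makeWaveform}} trace.
#'
#' @param spec a \linkS4class{WaveformSpec}.
#' @return named list: takeoff_ms, rise_ms, apd30_ms, apd50_ms, apd80_ms,
#'   apd_mxr_ms, apd_tri_ms. APD30 is where the waveform falls below 70\% of
#'   amplitude: \code{riseTime + (apd50 - riseTime) * 0.6^(1/plateauShape)}.
#' @export
waveformGroundTruth <- function(spec) {
  apd30 <- spec@riseTime +
    (spec@apd50 - spec@riseTime) * 0.6^(1 / spec@plateauShape)
  list(takeoff_ms = spec@takeoffTime, rise_ms = spec@riseTime,
       apd30_ms = apd30, apd50_ms = spec@apd50, apd80_ms = spec@apd80,
       apd_mxr_ms = spec@apdMxr, apd_tri_ms = spec@apdMxr - spec@apd50)
}

# disk centers of the tissue grid, in raster order
.grid_centers <- function(spec) {
  rr <- (seq_len(spec@gridRows) - 0.5) / spec@gridRows * spec@height
  cc <- (seq_len(spec@gridCols) - 0.5) / spec@gridCols * spec@width
  g <- expand.grid(col = cc, row = rr)  # col varies fastest -> raster order
  data.frame(row = g$row, col = g$col)
}

#' Generate a synthetic multi-tissue fluorescence movie
#'
#' Builds a movie of disk-shaped microtissues carrying AP trains, corrupted
#' the way the real recordings are: multiplicative exponential dye bleaching,
#' slow additive polynomial drift, a spatially non-uniform background, and
#' additive i.i.d. Gaussian noise. Inside a tissue disk the pixel trace is
#' \code{background + drift(t) + exp(-t/bleachTau) * waveform(t) + noise};
#' outside it is \code{background + drift(t) + noise}.
#'
#' @param spec a \linkS4class{MovieSpec}.
#' @param waveforms a single \linkS4class{WaveformSpec} recycled for all
#'   tissues, or a list with one spec per tissue (raster order).
#' @return list with elements \code{movie} (an \linkS4class{OpticalMovie}),
#'   \code{labels} (ground-truth label matrix), and \code{truth} (data.frame
#'   of per-tissue ground-truth metrics).
#' @export
makeMovie <- function(spec, waveforms = WaveformSpec()) {
  stopifnot(is(spec, "MovieSpec"))
  validObject(spec)
  centers <- .grid_centers(spec)
  k <- nrow(centers)
  if (is(waveforms, "WaveformSpec")) waveforms <- rep(list(waveforms), k)
  stopifnot(length(waveforms) == k)

  h <- spec@height; w <- spec@width; nf <- spec@nFrames
  t_ms <- (seq_len(nf) - 1) / spec@frameRate * 1000
  t_s <- t_ms / 1000

  # ground-truth label image
  labels <- matrix(0L, h, w)
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(k)) {
    d2 <- (rowg - centers$row[i])^2 + (colg - centers$col[i])^2
    labels[d2 <= spec@tissueRadius^2] <- i
  }

  # shared temporal components
  drift <- rep(0, nf)
  for (j in seq_along(spec@driftPoly))
    drift <- drift + spec@driftPoly[j] * t_s^(j - 1)
  bleach <- if (is.finite(spec@bleachTau)) exp(-t_s / spec@bleachTau)
            else rep(1, nf)
  bg <- spec@backgroundLevel *
    (1 + spec@backgroundSlope[1] * (rowg / h - 0.5) +
         spec@backgroundSlope[2] * (colg / w - 0.5))

  # per-tissue AP trains (one waveform per stimulus)
  trains <- matrix(0, nf, k)
  truth <- vector("list", k)
  for (i in seq_len(k)) {
    ws <- waveforms[[i]]
    tr <- rep(ws@restingLevel, nf)
    for (s in spec@stimTimes)
      tr <- tr + ws@amplitude *
        .waveform_fraction(ws, t_ms - s - ws@takeoffTime)
    trains[, i] <- tr
    gt <- waveformGroundTruth(ws)
    truth[[i]] <- data.frame(tissue = i, centroid_row = centers$row[i],
                             centroid_col = centers$col[i],
                             stim_delay_ms = gt$takeoff_ms,
                             rise_ms = gt$rise_ms, apd30_ms = gt$apd30_ms,
                             apd50_ms = gt$apd50_ms, apd80_ms = gt$apd80_ms,
                             apd_mxr_ms = gt$apd_mxr_ms,
                             apd_tri_ms = gt$apd_tri_ms,
                             amplitude = ws@amplitude)
  }

  data <- withSeed(spec@seed, {
    arr <- array(rnorm(h * w * nf, sd = spec@noiseSd), dim = c(h, w, nf))
    for (f in seq_len(nf)) {
      frame <- bg + drift[f]
      for (i in seq_len(k)) {
        idx <- labels == i
        frame[idx] <- frame[idx] + bleach[f] * trains[f, i]
      }
      arr[, , f] <- arr[, , f] + frame
    }
    arr
  })

  movie <- OpticalMovie(data, frameRate = spec@frameRate,
                        stimTimes = spec@stimTimes, pacingCL = spec@pacingCL)
  list(movie = movie, labels = labels, truth = do.call(rbind, truth))
}
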