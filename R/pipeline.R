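# End-to-end analysis: segmentation -> baseline correction and dF/F0 ->
# bilateral filtering -> MAS metric extraction, with a QC log.

#' Analyze a multi-tissue movie end to end
#'
#' Runs the full pipeline on an \linkS4class{OpticalMovie}: segments
#' individual microtissues from the FFT-amplitude image, averages each
#' region's pixel traces, removes baseline drift with the asymmetric least
#' squares fit, normalizes to dF/F0, applies the bilateral filter, and
#' measures per-beat AP metrics with the MAS detector.
#'
#' @param movie an \linkS4class{OpticalMovie} (stimulus times taken from the
#'   movie unless overridden).
#' @param stimTimes optional stimulus-time override, ms.
#' @param method threshold method for segmentation ("li" default, "otsu").
#' @param band pacing band, Hz (default derived from the pacing cycle
#'   length).
#' @param minArea minimum region area, px.
#' @param cfg MAS configuration.
#' @param offset camera dark offset subtracted before dF/F0.
#' @param bilateralWindow bilateral filter window (0 disables).
#' @param autoBeats detect beats from MAS maxima when no stimulus times are
#'   known.
#' @param ... further arguments to \code{\link{preprocessTrace}}.
#' @return list of class "cardiomapAnalysis": \code{regions}
#'   (\linkS4class{TissueRegionSet}), \code{traces} (list of processed
#'   \linkS4class{APTrace}), \code{beats} (per-beat metric data.frame with a
#'   tissue column), \code{summary} (per-tissue summary data.frame), and
#'   \code{qc} (thresholds, counts, settings).
#' @export
analyzeMovie <- function(movie, stimTimes = NULL, method = c("li", "otsu"),
                         band = NULL, minArea = 20, cfg = masConfig(),
                         offset = 0, bilateralWindow = 15, autoBeats = FALSE,
                         ...) {
  method <- match.arg(method)
  stopifnot(is(movie, "OpticalMovie"))
  if (is.null(stimTimes)) stimTimes <- movie@stimTimes
  regions <- segmentMovie(movie, method = method, band = band,
                          minArea = minArea)
  k <- nrow(regionTable(regions))
  if (k == 0) stop("no regions found: check the pacing band and threshold")
  sp <- 1000 / movie@frameRate
  traces <- vector("list", k)
  beats <- list()
  summaries <- list()
  for (i in seq_len(k)) {
    tr <- APTrace(regionTraces(regions)[, i], samplePeriod = sp,
                  stimTimes = stimTimes)
    tr <- preprocessTrace(tr, offset = offset, window = bilateralWindow, ...)
    traces[[i]] <- tr
    bm <- beatMetrics(tr, cfg = cfg, autoBeats = autoBeats)
    bm$beats$tissue <- i
    beats[[i]] <- bm$beats
    summaries[[i]] <- data.frame(tissue = i,
                                 as.data.frame(bm$summary))
  }
  structure(list(
    regions = regions, traces = traces,
    beats = do.call(rbind, beats),
    summary = do.call(rbind, summaries),
    qc = list(package_version = as.character(utils::packageVersion("cardiomap")),
              method = method, threshold = regions@threshold,
              n_regions = k, n_stimuli = length(stimTimes),
              min_area = minArea,
              n_inexcitable_beats = sum(!do.call(rbind, beats)$excitable))),
    class = "cardiomapAnalysis")
}

#' @export
print.cardiomapAnalysis <- function(x, ...) {
  cat("cardiomap analysis:", x$qc$n_regions, "regions (threshold",
      signif(x$qc$threshold, 4), ",", x$qc$method, ")\n")
  cat("per-tissue APD80 (ms):",
      paste(round(x$summary$apd80_ms, 1), collapse = ", "), "\n")
  invisible(x)
}
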