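# Readers and writers for the pipeline's external formats: multi-page TIFF
# or raw binary + JSON header for movies, CSV for traces and metric tables,
# JSON for summaries and ground truth.

#' Write a movie to disk
#'
#' Two formats are supported. \code{"tiff"} writes a grayscale multi-page
#' TIFF with intensities rescaled to [0, 1] (the scale is recorded in the
#' JSON sidecar; 32-bit float pages, so quantization is negligible).
#' \code{"raw"} writes the double-precision array verbatim
#' (little-endian, frame-major) next to a JSON header with
#' \{height, width, n_frames, dtype, frame_rate\}, and round-trips
#' bit-exactly. Both formats get a sidecar \code{<path>.json} carrying
#' frame_rate, stim_times and pacing_cl.
#'
#' @param movie an \linkS4class{OpticalMovie}.
#' @param path output file path (e.g. "movie.tif" or "movie.bin").
#' @param format "tiff" or "raw".
#' @return \code{path}, invisibly.
#' @export
writeMovie <- function(movie, path, format = c("tiff", "raw")) {
  format <- match.arg(format)
  d <- dim(movie@data)
  sidecar <- list(height = d[1], width = d[2], n_frames = d[3],
                  frame_rate = movie@frameRate,
                  stim_times = movie@stimTimes,
                  pacing_cl = movie@pacingCL, format = format)
  if (format == "tiff") {
    rng <- range(movie@data)
    scl <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(d[3]),
                    function(f) (movie@data[, , f] - rng[1]) / scl)
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
    sidecar$scale_min <- rng[1]
    sidecar$scale_range <- scl
  } else {
    sidecar$dtype <- "float64"
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(movie@data), con, size = 8, endian = "little")
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by \code{\link{writeMovie}}
#'
#' @param path movie file path; the sidecar \code{<path>.json} must exist.
#' @return an \linkS4class{OpticalMovie}.
#' @export
readMovie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- c(meta$height, meta$width, meta$n_frames)
  if (identical(meta$format, "raw")) {
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
    arr <- array(vals, dim = d)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = d)
    for (f in seq_len(d[3])) arr[, , f] <- pages[[f]]
    if (!is.null(meta$scale_range))
      arr <- arr * meta$scale_range + meta$scale_min
  }
  st <- if (is.null(meta$stim_times)) numeric(0) else
    as.numeric(meta$stim_times)
  OpticalMovie(arr, frameRate = meta$frame_rate, stimTimes = st,
               pacingCL = if (is.null(meta$pacing_cl)) NA_real_
                          else as.numeric(meta$pacing_cl))
}

#' Write per-region traces to CSV
#'
#' Columns: time_ms, region_1..region_k.
#'
#' @param regions a \linkS4class{TissueRegionSet} with traces, or a matrix.
#' @param path output CSV path.
#' @param samplePeriod ms per sample.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(regions, path, samplePeriod) {
  tr <- if (is(regions, "TissueRegionSet")) regions@traces else regions
  df <- data.frame(time_ms = (seq_len(nrow(tr)) - 1) * samplePeriod)
  df <- cbind(df, as.data.frame(tr))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV (time_ms, value columns)
#'
#' @param path CSV path.
#' @param stimTimes stimulus times, ms.
#' @return a list of \linkS4class{APTrace}, one per value column.
#' @export
readTraces <- function(path, stimTimes = numeric(0)) {
  df <- read.csv(path)
  stopifnot("time_ms" %in% names(df), nrow(df) >= 2)
  sp <- median(diff(df$time_ms))
  lapply(df[setdiff(names(df), "time_ms")], APTrace,
         samplePeriod = sp, stimTimes = stimTimes)
}

#' Write the 16-bit label image of a segmentation
#'
#' @param regions a \linkS4class{TissueRegionSet}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeLabelImage <- function(regions, path) {
  lab <- labelImage(regions)
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16)
  invisible(path)
}
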