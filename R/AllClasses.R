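#' OpticalMovie: a fluorescence voltage movie
#'
#' Container for a single optical-mapping field of view: a height x width x
#' frames intensity array with its acquisition frame rate, stimulus-pulse
#' times, and pacing cycle length.
#'
#' @slot data numeric array, height x width x n_frames (arbitrary
#'   fluorescence units).
#' @slot frameRate frames per second.
#' @slot stimTimes stimulus pulse times in ms from recording start (may be
#'   empty).
#' @slot pacingCL pacing cycle length in ms (NA when unpaced).
#' @export
setClass("OpticalMovie",
  representation(data = "array", frameRate = "numeric",
                 stimTimes = "numeric", pacingCL = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array (height x width x frames)")
    else if (dim(object@data)[3] < 2L)
      msg <- c(msg, "movie needs at least 2 frames")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (any(object@stimTimes < 0)) msg <- c(msg, "stimTimes must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an OpticalMovie
#'
#' @param data height x width x frames numeric array.
#' @param frameRate acquisition rate, frames/s.
#' @param stimTimes stimulus times, ms.
#' @param pacingCL pacing cycle length, ms. Defaults to the median stimulus
#'   interval when two or more stimulus times are given.
#' @return An \linkS4class{OpticalMovie}.
#' @export
OpticalMovie <- function(data, frameRate, stimTimes = numeric(0),
                         pacingCL = NA_real_) {
  if (is.na(pacingCL) && length(stimTimes) >= 2)
    pacingCL <- median(diff(sort(stimTimes)))
  new("OpticalMovie", data = data, frameRate = frameRate,
      stimTimes = as.numeric(stimTimes), pacingCL = as.numeric(pacingCL))
}

#' APTrace: a uniformly sampled action-potential trace
#'
#' @slot values trace values (raw fluorescence, dF/F0, or normalized voltage).
#' @slot samplePeriod sampling interval in ms.
#' @slot stimTimes stimulus times in ms relative to the first sample.
#' @slot polarity +1 when depolarization increases the value.
#' @export
setClass("APTrace",
  representation(values = "numeric", samplePeriod = "numeric",
                 stimTimes = "numeric", polarity = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) < 2L) msg <- c(msg, "trace needs >= 2 samples")
    if (length(object@samplePeriod) != 1L || object@samplePeriod <= 0)
      msg <- c(msg, "samplePeriod must be a single positive number")
    if (!object@polarity %in% c(-1, 1))
      msg <- c(msg, "polarity must be +1 or -1")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an APTrace
#'
#' @param values numeric trace.
#' @param samplePeriod sampling interval, ms.
#' @param stimTimes stimulus times, ms.
#' @param polarity +1 (default) when depolarization increases the value.
#' @return An \linkS4class{APTrace}.
#' @export
APTrace <- function(values, samplePeriod, stimTimes = numeric(0),
                    polarity = 1) {
  new("APTrace", values = as.numeric(values),
      samplePeriod = as.numeric(samplePeriod),
      stimTimes = as.numeric(stimTimes), polarity = polarity)
}

#' TissueRegionSet: labeled microtissue regions and their averaged traces
#'
#' @slot labelImage integer matrix of region labels (0 = background).
#' @slot regions data.frame with columns label, area, centroid_row,
#'   centroid_col.
#' @slot traces matrix (frames x regions) of per-region averaged traces;
#'   may have zero columns before traces are extracted.
#' @slot method thresholding method used ("li", "otsu", or "manual").
#' @slot threshold the threshold value applied to the FFT-amplitude image.
#' @export
setClass("TissueRegionSet",
  representation(labelImage = "matrix", regions = "data.frame",
                 traces = "matrix", method = "character",
                 threshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    k <- nrow(object@regions)
    if (k > 0 && !all(c("label", "area", "centroid_row", "centroid_col")
                      %in% names(object@regions)))
      msg <- c(msg, "regions must have label/area/centroid columns")
    if (ncol(object@traces) > 0 && ncol(object@traces) != k)
      msg <- c(msg, "traces must have one column per region")
    if (is.null(msg)) TRUE else msg
  })

#' WaveformSpec: parametric surrogate AP with closed-form ground truth
#'
#' Describes one synthetic action potential: a linear upstroke followed by a
#' piecewise plateau/repolarization whose fractional-repolarization crossing
#' times and late-repolarization corner are analytically known.
#'
#' @slot takeoffTime ms after the stimulus at which the upstroke starts.
#' @slot riseTime upstroke duration, ms.
#' @slot amplitude peak amplitude above resting level (>= 0).
#' @slot apd50,apd80,apdMxr repolarization landmarks, ms from takeoff.
#' @slot plateauShape exponent controlling phase-2 convexity (> 0).
#' @slot restingLevel resting fluorescence level.
#' @slot mxrLevel residual fraction of amplitude remaining at the
#'   late-repolarization corner.
#' @slot tailTau time constant, ms, of the slow tail after the corner.
#' @export
setClass("WaveformSpec",
  representation(takeoffTime = "numeric", riseTime = "numeric",
                 amplitude = "numeric", apd50 = "numeric", apd80 = "numeric",
                 apdMxr = "numeric", plateauShape = "numeric",
                 restingLevel = "numeric", mxrLevel = "numeric",
                 tailTau = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@riseTime <= 0) msg <- c(msg, "riseTime must be > 0")
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
    if (!(object@apd50 < object@apd80 && object@apd80 < object@apdMxr))
      msg <- c(msg, "non-monotone metric ordering: need apd50 < apd80 < apdMxr")
    if (object@riseTime >= object@apd50)
      msg <- c(msg, "riseTime must be shorter than apd50")
    if (object@plateauShape <= 0) msg <- c(msg, "plateauShape must be > 0")
    if (object@mxrLevel <= 0 || object@mxrLevel >= 0.2)
      msg <- c(msg, "mxrLevel must be in (0, 0.2)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a WaveformSpec
#'
#' @param takeoffTime,riseTime,amplitude,apd50,apd80,apdMxr,plateauShape,restingLevel,mxrLevel,tailTau
#'   see \linkS4class{WaveformSpec}.
#' @return A \linkS4class{WaveformSpec}.
#' @export
WaveformSpec <- function(takeoffTime = 10, riseTime = 5, amplitude = 1,
                         apd50 = 230, apd80 = 272, apdMxr = 307,
                         plateauShape = 2, restingLevel = 0,
                         mxrLevel = 0.05, tailTau = 40) {
  new("WaveformSpec", takeoffTime = takeoffTime, riseTime = riseTime,
      amplitude = amplitude, apd50 = apd50, apd80 = apd80, apdMxr = apdMxr,
      plateauShape = plateauShape, restingLevel = restingLevel,
      mxrLevel = mxrLevel, tailTau = tailTau)
}

#' MovieSpec: layout and corruption model for a synthetic movie
#'
#' @slot height,width frame size in pixels.
#' @slot nFrames number of frames.
#' @slot frameRate frames/s.
#' @slot gridRows,gridCols microtissue grid layout.
#' @slot tissueRadius disk radius, pixels.
#' @slot pacingCL pacing cycle length, ms.
#' @slot stimTimes stimulus times, ms.
#' @slot bleachTau exponential dye-bleaching time constant, s (Inf = none).
#' @slot driftPoly polynomial coefficients (intercept first) of the slow
#'   additive drift, evaluated on time in seconds.
#' @slot backgroundLevel mean background fluorescence.
#' @slot backgroundSlope length-2 relative gradient (row, col) of the
#'   background across the frame.
#' @slot noiseSd additive Gaussian noise SD per pixel-frame.
#' @slot seed RNG seed; a fixed seed makes the movie bit-reproducible.
#' @export
setClass("MovieSpec",
  representation(height = "numeric", width = "numeric", nFrames = "numeric",
                 frameRate = "numeric", gridRows = "numeric",
                 gridCols = "numeric", tissueRadius = "numeric",
                 pacingCL = "numeric", stimTimes = "numeric",
                 bleachTau = "numeric", driftPoly = "numeric",
                 backgroundLevel = "numeric", backgroundSlope = "numeric",
                 noiseSd = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    dur_ms <- object@nFrames / object@frameRate * 1000
    if (dur_ms < 2 * object@pacingCL)
      msg <- c(msg, "movie must cover at least 2 pacing cycles")
    sr <- (object@height - 1) / (object@gridRows * 2)
    sc <- (object@width - 1) / (object@gridCols * 2)
    if (object@tissueRadius >= min(sr, sc))
      msg <- c(msg, "tissue disks overlap or leave the frame")
    if (length(object@backgroundSlope) != 2L)
      msg <- c(msg, "backgroundSlope must have length 2")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a MovieSpec
#'
#' Defaults emulate the acquisition geometry of the platform: a 4x4 grid of
#' microtissues in a 100x100 px field of view imaged at 1000 frames/s, paced
#' at 1 Hz, with exponential dye bleaching, slow additive perfusion drift,
#' a non-uniform background and additive Gaussian noise.
#'
#' @param height,width,nFrames,frameRate,gridRows,gridCols,tissueRadius,pacingCL,stimTimes,bleachTau,driftPoly,backgroundLevel,backgroundSlope,noiseSd,seed
#'   see \linkS4class{MovieSpec}.
#' @return A \linkS4class{MovieSpec}.
#' @export
MovieSpec <- function(height = 100, width = 100, nFrames = 4000,
                      frameRate = 1000, gridRows = 4, gridCols = 4,
                      tissueRadius = 8, pacingCL = 1000,
                      stimTimes = NULL, bleachTau = 30,
                      driftPoly = c(0, 0), backgroundLevel = 0.2,
                      backgroundSlope = c(0.3, 0.2), noiseSd = 0.02,
                      seed = 1) {
  if (is.null(stimTimes)) {
    dur_ms <- nFrames / frameRate * 1000
    stimTimes <- seq(0, dur_ms - pacingCL, by = pacingCL)
  }
  new("MovieSpec", height = height, width = width, nFrames = nFrames,
      frameRate = frameRate, gridRows = gridRows, gridCols = gridCols,
      tissueRadius = tissueRadius, pacingCL = pacingCL,
      stimTimes = as.numeric(stimTimes), bleachTau = bleachTau,
      driftPoly = as.numeric(driftPoly), backgroundLevel = backgroundLevel,
      backgroundSlope = as.numeric(backgroundSlope), noiseSd = noiseSd,
      seed = seed)
}
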