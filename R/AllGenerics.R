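#' Accessors for movie and trace objects
#'
#' @param x an \linkS4class{OpticalMovie}, \linkS4class{APTrace} or
#'   \linkS4class{TissueRegionSet}.
#' @return The requested component: the intensity array (\code{movieData}),
#'   the frame rate in frames/s (\code{frameRate}), stimulus times in ms
#'   (\code{stimTimes}), trace values (\code{traceValues}), the sampling
#'   interval in ms (\code{samplePeriod}), the region table
#'   (\code{regionTable}), the label image (\code{labelImage}) or the
#'   frames x regions trace matrix (\code{regionTraces}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("stimTimes", function(x) standardGeneric("stimTimes"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("samplePeriod", function(x) standardGeneric("samplePeriod"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @rdname accessors
#' @export
setGeneric("regionTraces", function(x) standardGeneric("regionTraces"))

#' @rdname accessors
#' @export
setMethod("movieData", "OpticalMovie", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("frameRate", "OpticalMovie", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("stimTimes", "OpticalMovie", function(x) x@stimTimes)
#' @rdname accessors
#' @export
setMethod("stimTimes", "APTrace", function(x) x@stimTimes)
#' @rdname accessors
#' @export
setMethod("traceValues", "APTrace", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("samplePeriod", "APTrace", function(x) x@samplePeriod)
#' @rdname accessors
#' @export
setMethod("regionTable", "TissueRegionSet", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("labelImage", "TissueRegionSet", function(x) x@labelImage)
#' @rdname accessors
#' @export
setMethod("regionTraces", "TissueRegionSet", function(x) x@traces)

setMethod("show", "OpticalMovie", function(object) {
  d <- dim(object@data)
  cat("OpticalMovie:", d[1], "x", d[2], "px,", d[3], "frames @",
      object@frameRate, "fps\n")
  cat("  duration:", round(d[3] / object@frameRate, 3), "s;",
      length(object@stimTimes), "stimuli; pacing CL:",
      object@pacingCL, "ms\n")
})

setMethod("show", "APTrace", function(object) {
  cat("APTrace:", length(object@values), "samples @",
      object@samplePeriod, "ms;", length(object@stimTimes), "stimuli\n")
})

setMethod("show", "TissueRegionSet", function(object) {
  cat("TissueRegionSet:", nrow(object@regions), "regions (method:",
      object@method, ", threshold:", signif(object@threshold, 4), ")\n")
  if (nrow(object@regions) > 0) {
    cat("  areas:", paste(object@regions$area, collapse = ", "), "px\n")
  }
})
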