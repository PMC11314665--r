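# Generics and show/accessor methods for the core classes.

#' @rdname ClassTaxonomy-class
#' @param x,object A `ClassTaxonomy`.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname ClassTaxonomy-class
#' @export
setMethod("classNames", "ClassTaxonomy", function(x) x@classes$name)

#' @rdname ClassTaxonomy-class
#' @export
setMethod("length", "ClassTaxonomy", function(x) nrow(x@classes))

#' @describeIn ClassTaxonomy-class taxonomy table as a data.frame.
#' @param row.names,optional,... Passed on as in [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "ClassTaxonomy",
  function(x, row.names = NULL, optional = FALSE, ...) x@classes)

setMethod("show", "ClassTaxonomy", function(object) {
  cls <- object@classes
  cat("ClassTaxonomy with", nrow(cls), "classes in",
      length(unique(cls$category)), "categories\n")
  cat("  privacy:  ", paste(cls$name[grepl("privacy", cls$roles)], collapse = ", "), "\n")
  cat("  fall_risk:", paste(cls$name[grepl("fall_risk", cls$roles)], collapse = ", "), "\n")
})

#' @rdname WalkingPath-class
#' @param x,object A `WalkingPath`.
#' @export
setGeneric("pathVertices", function(x) standardGeneric("pathVertices"))

#' @rdname WalkingPath-class
#' @export
setMethod("pathVertices", "WalkingPath", function(x) x@vertices)

setMethod("show", "WalkingPath", function(object) {
  v <- object@vertices
  cat(sprintf("WalkingPath in a %g x %g frame\n", object@frameWidth, object@frameHeight))
  cat(sprintf("  base  y=%g: x in [%g, %g]\n", v[1, 2], v[1, 1], v[2, 1]))
  cat(sprintf("  top   y=%g: x in [%g, %g]\n", v[4, 2], v[4, 1], v[3, 1]))
})

#' @rdname BinaryMask-class
#' @param x,object A `BinaryMask`.
#' @export
setGeneric("maskBits", function(x) standardGeneric("maskBits"))

#' @rdname BinaryMask-class
#' @export
setMethod("maskBits", "BinaryMask", function(x) x@bits)

#' @describeIn BinaryMask-class mask resolution as `c(width, height)` cells.
#' @export
setGeneric("maskResolution", function(x) standardGeneric("maskResolution"))

#' @rdname BinaryMask-class
#' @export
setMethod("maskResolution", "BinaryMask",
  function(x) c(ncol(x@bits), nrow(x@bits)))

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d cells over a %g x %g px frame (%d set)\n",
              ncol(object@bits), nrow(object@bits),
              object@frameWidth, object@frameHeight, sum(object@bits)))
})

setMethod("show", "FrameRecord", function(object) {
  cat(sprintf("FrameRecord #%d @ %.3fs (%g x %g px): %d detection(s), gaze %s\n",
              object@index, object@timestamp, object@width, object@height,
              nrow(object@detections),
              if (object@gazeValid) sprintf("(%.0f, %.0f)", object@gazeX, object@gazeY)
              else "invalid"))
})

#' @rdname FrameRecord-class
#' @param x,object A `FrameRecord`.
#' @export
setGeneric("frameDetections", function(x) standardGeneric("frameDetections"))

#' @rdname FrameRecord-class
#' @export
setMethod("frameDetections", "FrameRecord", function(x) x@detections)

setMethod("show", "AccelSignal", function(object) {
  cat(sprintf("AccelSignal: %d samples @ %g Hz (%.1f s), units %s\n",
              length(object@time), object@sampleRate,
              diff(range(object@time)), object@units))
})

#' @rdname AccelSignal-class
#' @param x,object An `AccelSignal`.
#' @export
setMethod("length", "AccelSignal", function(x) length(x@time))

#' @rdname GaitEvents-class
#' @param x,object A `GaitEvents`.
#' @export
setGeneric("icTimes", function(x) standardGeneric("icTimes"))

#' @rdname GaitEvents-class
#' @export
setMethod("icTimes", "GaitEvents", function(x) x@ic)

#' @describeIn GaitEvents-class final-contact times.
#' @export
setGeneric("fcTimes", function(x) standardGeneric("fcTimes"))

#' @rdname GaitEvents-class
#' @export
setMethod("fcTimes", "GaitEvents", function(x) x@fc)

setMethod("show", "GaitEvents", function(object) {
  cat(sprintf("GaitEvents: %d IC, %d FC", length(object@ic), length(object@fc)))
  if (length(object@ic) > 1) {
    cat(sprintf(" (mean step %.3f s)", mean(diff(object@ic))))
  }
  cat("\n")
})

#' @rdname GaitStats-class
#' @param x,object A `GaitStats`.
#' @export
setGeneric("statsMatrix", function(x) standardGeneric("statsMatrix"))

#' @rdname GaitStats-class
#' @export
setMethod("statsMatrix", "GaitStats", function(x) x@values)

#' @describeIn GaitStats-class one-row data.frame with columns like
#'   `step_mean`, `step_std`, `step_asy`, ..., `swing_asy`.
#' @param row.names,optional,... Passed on as in [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "GaitStats",
  function(x, row.names = NULL, optional = FALSE, ...) {
    v <- x@values
    out <- as.data.frame(as.list(t(v)))
    names(out) <- paste(rep(rownames(v), each = 3), colnames(v), sep = "_")
    out
  })

setMethod("show", "GaitStats", function(object) {
  cat("Temporal gait characteristics (s):\n")
  print(round(object@values, 3))
})
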