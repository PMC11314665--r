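#' @import methods
NULL

ROLE_TOKENS <- c("context", "fall_risk", "privacy")

# ---------------------------------------------------------------------------
# ClassTaxonomy

#' Object-class taxonomy for egocentric scene understanding
#'
#' An ordered set of object classes, each carrying a category number (1-4)
#' and one or more roles: `context` (explains gait fluctuations), `fall_risk`
#' (potential extrinsic hazard) and/or `privacy` (must be anonymized). The
#' built-in taxonomy ships 18 classes in 4 categories; see [loadTaxonomy()].
#'
#' @slot classes A `data.frame` with columns `name`, `category`, `roles`
#'   (comma-separated role tokens) and `rationale`, one row per class, in
#'   taxonomy order.
#' @seealso [loadTaxonomy()], [isPrivacyClass()], [isHazardClass()]
#' @export
setClass("ClassTaxonomy", representation(classes = "data.frame"))

validTaxonomy <- function(object) {
  cls <- object@classes
  msgs <- character(0)
  needed <- c("name", "category", "roles", "rationale")
  if (!all(needed %in% names(cls))) {
    return(paste("classes must have columns", paste(needed, collapse = ", ")))
  }
  if (nrow(cls) == 0) msgs <- c(msgs, "taxonomy has no classes")
  nm <- trimws(cls$name)
  if (any(!nzchar(nm))) msgs <- c(msgs, "empty class name")
  if (anyDuplicated(tolower(nm))) {
    msgs <- c(msgs, paste0("duplicate class name(s): ",
                           paste(unique(nm[duplicated(tolower(nm))]), collapse = ", ")))
  }
  if (!all(cls$category %in% 1:4)) msgs <- c(msgs, "category must be an integer in 1..4")
  roleList <- strsplit(cls$roles, ",", fixed = TRUE)
  for (i in seq_along(roleList)) {
    r <- trimws(roleList[[i]])
    if (length(r) == 0 || any(!nzchar(r))) {
      msgs <- c(msgs, paste0("class '", nm[i], "' has no roles"))
    } else if (!all(r %in% ROLE_TOKENS)) {
      msgs <- c(msgs, paste0("class '", nm[i], "' has unknown role token(s): ",
                             paste(setdiff(r, ROLE_TOKENS), collapse = ", ")))
    } else if (cls$category[i] == 4 && !"privacy" %in% r) {
      msgs <- c(msgs, paste0("category-4 class '", nm[i], "' must carry the privacy role"))
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("ClassTaxonomy", validTaxonomy)

# ---------------------------------------------------------------------------
# WalkingPath

#' Trapezoidal model of the wearer's immediate walking path
#'
#' The immediate forward walking path is modelled as a perspective-warped
#' rectangle (isosceles trapezoid) in scene-camera pixel coordinates: wide at
#' the bottom of the frame (directly in front of the wearer) and narrower
#' towards the top, reflecting the converging forward view. Construct with
#' [buildWalkingPath()].
#'
#' @slot vertices 4 x 2 numeric matrix of (x, y) pixel coordinates, ordered
#'   bottom-left, bottom-right, top-right, top-left.
#' @slot frameWidth,frameHeight Frame dimensions in pixels.
#' @export
setClass("WalkingPath",
  representation(vertices = "matrix", frameWidth = "numeric",
                 frameHeight = "numeric"))

setValidity("WalkingPath", function(object) {
  v <- object@vertices
  msgs <- character(0)
  if (!is.numeric(v) || !identical(dim(v), c(4L, 2L))) {
    return("vertices must be a 4 x 2 numeric matrix")
  }
  W <- object@frameWidth
  H <- object@frameHeight
  if (length(W) != 1 || length(H) != 1 || W <= 0 || H <= 0) {
    return("frame dimensions must be positive scalars")
  }
  tol <- 1e-6
  if (abs(v[1, 2] - H) > tol || abs(v[2, 2] - H) > tol) {
    msgs <- c(msgs, "bottom edge must lie on the frame's bottom row")
  }
  if (abs((v[1, 1] + v[2, 1]) / 2 - W / 2) > tol ||
      abs((v[3, 1] + v[4, 1]) / 2 - W / 2) > tol) {
    msgs <- c(msgs, "path must be horizontally centred and symmetric")
  }
  if (v[2, 1] - v[1, 1] < v[3, 1] - v[4, 1] - tol) {
    msgs <- c(msgs, "top edge wider than base (perspective must converge)")
  }
  if (v[3, 2] > H + tol || v[3, 2] < 0 || abs(v[3, 2] - v[4, 2]) > tol) {
    msgs <- c(msgs, "top edge must be horizontal and inside the frame")
  }
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# BinaryMask

#' Downscaled binary occupancy mask
#'
#' A rectangular grid of 0/1 cells covering the full frame, used for
#' object x path x gaze overlap detection at reduced resolution (default
#' 200 x 200 cells). Cell `[i, j]` covers the full-frame pixel footprint
#' `[(j-1) W/wm, j W/wm) x [(i-1) H/hm, i H/hm)` and is set when that
#' footprint intersects the rasterized shape (outward rounding, so masks are
#' supersets of the underlying shape). Construct with [rasterize()].
#'
#' @slot bits Logical matrix, rows = mask cells along y, columns along x.
#' @slot frameWidth,frameHeight Full-frame pixel dimensions the mask maps to.
#' @export
setClass("BinaryMask",
  representation(bits = "matrix", frameWidth = "numeric",
                 frameHeight = "numeric"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@bits)) return("bits must be a logical matrix")
  if (anyNA(object@bits)) return("bits must not contain NA")
  if (object@frameWidth <= 0 || object@frameHeight <= 0) {
    return("frame dimensions must be positive")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# FrameRecord

#' One egocentric video frame's detections and gaze sample
#'
#' Bundles everything known about a single scene-camera frame: its index and
#' timestamp, pixel dimensions, the object detections (a data.frame with
#' columns `class`, `x_min`, `y_min`, `x_max`, `y_max`, `confidence`), and an
#' optional gaze sample in scene-camera pixels. A missing or off-frame gaze
#' sample is represented by `gazeValid = FALSE`.
#'
#' @slot index Integer frame index (>= 0).
#' @slot timestamp Seconds.
#' @slot width,height Frame dimensions in pixels.
#' @slot detections Detection table (possibly zero rows).
#' @slot gazeX,gazeY Gaze coordinates in pixels (may be `NA` when invalid).
#' @slot gazeValid Logical flag.
#' @export
setClass("FrameRecord",
  representation(index = "integer", timestamp = "numeric",
                 width = "numeric", height = "numeric",
                 detections = "data.frame",
                 gazeX = "numeric", gazeY = "numeric", gazeValid = "logical"))

setValidity("FrameRecord", function(object) {
  msgs <- character(0)
  if (object@index < 0) msgs <- c(msgs, "index must be >= 0")
  if (object@width <= 0 || object@height <= 0) {
    msgs <- c(msgs, "frame dimensions must be positive")
  }
  d <- object@detections
  if (nrow(d) > 0) {
    ok <- tryCatch({assertDetections(d); TRUE}, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
  }
  if (isTRUE(object@gazeValid)) {
    if (is.na(object@gazeX) || is.na(object@gazeY) ||
        object@gazeX < 0 || object@gazeX >= object@width ||
        object@gazeY < 0 || object@gazeY >= object@height) {
      msgs <- c(msgs, "valid gaze sample must lie inside the frame")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FrameRecord
#'
#' @param index Frame index (>= 0).
#' @param timestamp Frame timestamp in seconds.
#' @param width,height Frame dimensions in pixels.
#' @param detections Detection data.frame (`class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence`); defaults to none.
#' @param gazeX,gazeY Gaze coordinates in scene-camera pixels, or `NA`.
#' @param gazeValid Whether the gaze sample is usable; defaults to `TRUE`
#'   when both coordinates are given. Gaze coordinates are clipped to the
#'   frame interior.
#' @return A [FrameRecord-class] object.
#' @export
#' @examples
#' FrameRecord(0, 0.0, 640, 480,
#'   detections = data.frame(class = "Chair", x_min = 10, y_min = 20,
#'                           x_max = 110, y_max = 140, confidence = 0.9),
#'   gazeX = 320, gazeY = 400)
FrameRecord <- function(index, timestamp, width, height,
                        detections = emptyDetections(),
                        gazeX = NA_real_, gazeY = NA_real_,
                        gazeValid = !is.na(gazeX) && !is.na(gazeY)) {
  if (isTRUE(gazeValid)) {
    # clipping policy: snap marginally off-frame samples onto the frame edge
    gazeX <- min(max(gazeX, 0), width - 1e-9)
    gazeY <- min(max(gazeY, 0), height - 1e-9)
  }
  new("FrameRecord", index = as.integer(index), timestamp = as.numeric(timestamp),
      width = as.numeric(width), height = as.numeric(height),
      detections = detections, gazeX = as.numeric(gazeX),
      gazeY = as.numeric(gazeY), gazeValid = isTRUE(gazeValid))
}

# ---------------------------------------------------------------------------
# AccelSignal

#' Tri-axial lower-back accelerometer signal
#'
#' Uniformly sampled acceleration from a wearable at the lower back (L5),
#' with vertical (`v`), anteroposterior (`ap`) and mediolateral (`ml`)
#' channels. Units are either `"m/s^2"` or `"g"` (declared, not guessed).
#'
#' @slot time Numeric vector of timestamps in seconds (uniform grid).
#' @slot acc Numeric matrix with columns `v`, `ap`, `ml`.
#' @slot sampleRate Sampling rate in Hz.
#' @slot units `"m/s^2"` or `"g"`.
#' @export
setClass("AccelSignal",
  representation(time = "numeric", acc = "matrix", sampleRate = "numeric",
                 units = "character"))

setValidity("AccelSignal", function(object) {
  msgs <- character(0)
  n <- length(object@time)
  if (n < 2) msgs <- c(msgs, "signal must have at least 2 samples")
  if (!identical(colnames(object@acc), c("v", "ap", "ml"))) {
    msgs <- c(msgs, "acc must have columns v, ap, ml")
  }
  if (nrow(object@acc) != n) msgs <- c(msgs, "time and acc lengths differ")
  if (!object@units %in% c("m/s^2", "g")) {
    msgs <- c(msgs, "units must be 'm/s^2' or 'g'")
  }
  if (n >= 2) {
    dt <- diff(object@time)
    if (any(dt <= 0)) {
      msgs <- c(msgs, "timestamps must be strictly increasing")
    } else if ((max(dt) - min(dt)) > 1e-6 * mean(dt)) {
      msgs <- c(msgs, "sampling must be uniform within 1e-6 relative tolerance")
    }
    if (abs(object@sampleRate * mean(dt) - 1) > 1e-4) {
      msgs <- c(msgs, "sampleRate inconsistent with timestamp spacing")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AccelSignal
#'
#' @param time Timestamps in seconds (uniform grid), or `NULL` to build one
#'   from `sampleRate` starting at 0.
#' @param v,ap,ml Vertical, anteroposterior and mediolateral acceleration.
#' @param sampleRate Sampling rate in Hz; inferred from `time` if omitted.
#' @param units `"m/s^2"` (default) or `"g"`.
#' @return An [AccelSignal-class] object.
#' @export
AccelSignal <- function(time = NULL, v, ap = numeric(length(v)),
                        ml = numeric(length(v)), sampleRate = NULL,
                        units = "m/s^2") {
  n <- length(v)
  if (is.null(time)) {
    if (is.null(sampleRate)) stop("either time or sampleRate must be given")
    time <- (seq_len(n) - 1) / sampleRate
  }
  if (is.null(sampleRate)) sampleRate <- 1 / mean(diff(time))
  acc <- cbind(v = as.numeric(v), ap = as.numeric(ap), ml = as.numeric(ml))
  new("AccelSignal", time = as.numeric(time), acc = acc,
      sampleRate = sampleRate, units = units)
}

# ---------------------------------------------------------------------------
# GaitEvents

#' Initial- and final-contact gait events
#'
#' Times (seconds) of initial contacts (IC, heel strike) and final contacts
#' (FC, toe off) detected within one walking bout. After validation each FC
#' lies strictly between two consecutive ICs, with at most one FC per
#' inter-IC gap, so the merged event sequence alternates IC, FC, IC, FC, ...
#' (the gap after the first IC may lack an FC when the corresponding stride
#' began before the bout).
#'
#' @slot ic,fc Numeric vectors of event times in seconds, sorted ascending.
#' @export
setClass("GaitEvents", representation(ic = "numeric", fc = "numeric"))

setValidity("GaitEvents", function(object) {
  msgs <- character(0)
  if (is.unsorted(object@ic, strictly = TRUE) && length(object@ic) > 1) {
    msgs <- c(msgs, "ic times must be strictly increasing")
  }
  if (is.unsorted(object@fc, strictly = TRUE) && length(object@fc) > 1) {
    msgs <- c(msgs, "fc times must be strictly increasing")
  }
  if (length(object@ic) >= 2 && length(object@fc) > 0) {
    gap <- findInterval(object@fc, object@ic)
    if (any(gap < 1) || any(gap >= length(object@ic))) {
      msgs <- c(msgs, "every fc must lie between two consecutive ic events")
    } else if (anyDuplicated(gap)) {
      msgs <- c(msgs, "alternation violated: more than one fc between consecutive ic events")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GaitEvents object
#'
#' @param ic,fc Initial/final contact times in seconds.
#' @return A [GaitEvents-class] object.
#' @export
GaitEvents <- function(ic = numeric(0), fc = numeric(0)) {
  new("GaitEvents", ic = as.numeric(sort(ic)), fc = as.numeric(sort(fc)))
}

# ---------------------------------------------------------------------------
# GaitStats

#' Temporal gait characteristics
#'
#' Mean, standard deviation (STD) and asymmetry (Asy.) of step, stance and
#' swing times, all in seconds, as computed by [computeTemporalStats()].
#' Asymmetry is the absolute difference between the means of alternating
#' (proxy left/right) elements of each series.
#'
#' @slot values 3 x 3 numeric matrix, rows `step`, `stance`, `swing`,
#'   columns `mean`, `std`, `asy`.
#' @slot n Integer vector of series lengths, named by row.
#' @export
setClass("GaitStats", representation(values = "matrix", n = "integer"))

setValidity("GaitStats", function(object) {
  if (!identical(rownames(object@values), c("step", "stance", "swing")) ||
      !identical(colnames(object@values), c("mean", "std", "asy"))) {
    return("values must be a 3x3 matrix with rows step/stance/swing and columns mean/std/asy")
  }
  v <- object@values
  if (any(!is.na(v) & v < 0)) return("temporal statistics must be non-negative")
  TRUE
})
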