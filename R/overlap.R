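# Mask-based overlap engine: rasterization of boxes, gaze circles and the
# walking path onto a downscaled grid, and per-detection overlap verdicts.

# Mask-cell index range covered by a pixel interval [lo, hi) on an axis of
# `fullSize` pixels downscaled to `cells` cells, with outward rounding (floor
# on minima, ceil on maxima) so the rasterized mask is a superset of the
# shape. Returns c(first, last) cell (1-based), or NULL when empty.
cellRange <- function(lo, hi, fullSize, cells) {
  lo <- max(lo, 0)
  hi <- min(hi, fullSize)
  if (lo >= hi) return(NULL)
  c(floor(lo * cells / fullSize) + 1L, ceiling(hi * cells / fullSize))
}

#' Rasterize a shape onto a downscaled binary mask
#'
#' Converts a bounding box, a gaze circle or a [WalkingPath-class] trapezoid
#' into a [BinaryMask-class] at the requested resolution (default 200 x 200
#' cells). A cell is set if and only if its full-frame pixel footprint
#' intersects the shape, using outward rounding, so the mask is always a
#' superset of the shape: downscaling can introduce marginal false-positive
#' overlaps but never misses a true one.
#'
#' Shapes fully outside the frame rasterize to an all-zero mask.
#'
#' @param shape One of: a numeric bounding box `c(x_min, y_min, x_max,
#'   y_max)` (0-based half-open pixel intervals), a circle given as
#'   `list(center = c(x, y), radius = r)`, or a [WalkingPath-class].
#' @param frameWidth,frameHeight Frame dimensions in pixels; taken from the
#'   path for `WalkingPath` input.
#' @param resolution Mask resolution `c(width, height)` in cells,
#'   default `c(200, 200)`.
#' @return A [BinaryMask-class].
#' @export
#' @examples
#' m <- rasterize(c(0, 0, 640, 480), 640, 480)
#' all(maskBits(m))
rasterize <- function(shape, frameWidth = NULL, frameHeight = NULL,
                      resolution = c(200, 200)) {
  if (any(resolution < 1)) stop("mask resolution must be >= 1 cell")
  wm <- as.integer(resolution[1L])
  hm <- as.integer(resolution[2L])
  if (is(shape, "WalkingPath")) {
    return(rasterizePath(shape, wm, hm))
  }
  if (is.null(frameWidth) || is.null(frameHeight) ||
      frameWidth <= 0 || frameHeight <= 0) {
    stop("positive frame dimensions are required")
  }
  bits <- matrix(FALSE, nrow = hm, ncol = wm)
  if (is.list(shape) && all(c("center", "radius") %in% names(shape))) {
    if (shape$radius <= 0) stop("circle radius must be positive")
    bits <- circleBits(shape$center[1L], shape$center[2L], shape$radius,
                       frameWidth, frameHeight, wm, hm)
  } else {
    assertBox(shape)
    jr <- cellRange(shape[1L], shape[3L], frameWidth, wm)
    ir <- cellRange(shape[2L], shape[4L], frameHeight, hm)
    if (!is.null(jr) && !is.null(ir)) {
      bits[ir[1L]:ir[2L], jr[1L]:jr[2L]] <- TRUE
    }
  }
  new("BinaryMask", bits = bits, frameWidth = as.numeric(frameWidth),
      frameHeight = as.numeric(frameHeight))
}

# Cell is set iff the closed cell footprint rectangle intersects the disk
# (clamped-point distance test), vectorized over the grid.
circleBits <- function(cx, cy, r, frameWidth, frameHeight, wm, hm) {
  xEdges <- (0:wm) * frameWidth / wm
  yEdges <- (0:hm) * frameHeight / hm
  dx <- pmax(0, xEdges[-length(xEdges)] - cx, cx - xEdges[-1L])
  dy <- pmax(0, yEdges[-length(yEdges)] - cy, cy - yEdges[-1L])
  outer(dy^2, dx^2, "+") <= r^2
}

# The trapezoid's x-extent is nested and widens towards the frame bottom, so
# a cell row's coverage equals the extent at the deepest y it reaches.
rasterizePath <- function(path, wm, hm) {
  W <- path@frameWidth
  H <- path@frameHeight
  v <- path@vertices
  topY <- v[4L, 2L]
  bits <- matrix(FALSE, nrow = hm, ncol = wm)
  for (i in seq_len(hm)) {
    y0 <- (i - 1) * H / hm
    y1 <- i * H / hm
    if (y1 <= topY) next
    xr <- pathXRange(path, min(y1, H))
    jr <- cellRange(xr[1L], xr[2L], W, wm)
    if (!is.null(jr)) bits[i, jr[1L]:jr[2L]] <- TRUE
  }
  new("BinaryMask", bits = bits, frameWidth = W, frameHeight = H)
}

#' Detect object/path and object/gaze overlaps for one frame
#'
#' For every detection in the frame, rasterizes the object's bounding box,
#' the walking-path trapezoid and the gaze point (a filled circle of
#' `gazeRadius` pixels) onto downscaled binary masks and reports whether the
#' object mask shares any set cell with the path mask (`in_path`) and with
#' the gaze mask (`gazed`). A missing or invalid gaze sample yields
#' `gazed = FALSE` for all detections (eye trackers drop samples routinely).
#'
#' Masks use outward rounding, so a true overlap is never missed; verdicts
#' can differ from full-resolution geometry only for overlaps or near-misses
#' thinner than about one mask cell. With `maskResolution` equal to the frame
#' resolution the verdicts match per-pixel geometry exactly.
#'
#' @param frame A [FrameRecord-class].
#' @param path A [WalkingPath-class] built for the same frame size.
#' @param maskResolution Mask resolution `c(width, height)`, default
#'   `c(200, 200)` cells.
#' @param gazeRadius Gaze circle radius in full-frame pixels, default 30.
#' @param pathMask Optional precomputed path [BinaryMask-class] (reused
#'   across frames of identical geometry for speed).
#' @return The frame's detection data.frame with logical columns `in_path`
#'   and `gazed` appended; the frame-level flag `gaze_on_path` (gaze circle
#'   intersects the path) is attached as attribute `"gaze_on_path"`.
#' @export
#' @examples
#' fr <- FrameRecord(0, 0, 640, 480,
#'   detections = data.frame(class = "Chair", x_min = 280, y_min = 380,
#'                           x_max = 380, y_max = 470, confidence = 0.8),
#'   gazeX = 320, gazeY = 420)
#' detectOverlaps(fr, buildWalkingPath(640, 480))
detectOverlaps <- function(frame, path, maskResolution = c(200, 200),
                           gazeRadius = 30, pathMask = NULL) {
  stopifnot(is(frame, "FrameRecord"), is(path, "WalkingPath"))
  if (path@frameWidth != frame@width || path@frameHeight != frame@height) {
    stop("walking path was built for a different frame size")
  }
  wm <- as.integer(maskResolution[1L])
  hm <- as.integer(maskResolution[2L])
  if (is.null(pathMask)) pathMask <- rasterize(path, resolution = c(wm, hm))
  pathBits <- pathMask@bits
  eyeBits <- NULL
  if (frame@gazeValid) {
    eyeBits <- circleBits(frame@gazeX, frame@gazeY, gazeRadius,
                          frame@width, frame@height, wm, hm)
  }
  det <- frame@detections
  n <- nrow(det)
  inPath <- logical(n)
  gazed <- logical(n)
  for (k in seq_len(n)) {
    box <- clipBox(as.numeric(det[k, c("x_min", "y_min", "x_max", "y_max")]),
                   frame@width, frame@height)
    if (is.null(box)) next
    jr <- cellRange(box[1L], box[3L], frame@width, wm)
    ir <- cellRange(box[2L], box[4L], frame@height, hm)
    if (is.null(jr) || is.null(ir)) next
    rows <- ir[1L]:ir[2L]
    cols <- jr[1L]:jr[2L]
    inPath[k] <- any(pathBits[rows, cols])
    if (!is.null(eyeBits)) gazed[k] <- any(eyeBits[rows, cols])
  }
  verdicts <- det
  verdicts$in_path <- inPath
  verdicts$gazed <- gazed
  attr(verdicts, "gaze_on_path") <-
    if (is.null(eyeBits)) FALSE else any(eyeBits & pathBits)
  verdicts
}

#' Summarize one frame's overlap verdicts
#'
#' Aggregates per-detection verdicts into frame-level context flags:
#' `hazard_in_path` (any fall-risk-role detection overlaps the walking path),
#' `hazard_gazed` (any such in-path hazard is also gazed) and `gaze_on_path`
#' (the gaze circle itself intersects the path).
#'
#' @param verdicts A verdict data.frame from [detectOverlaps()].
#' @param taxonomy A [ClassTaxonomy-class] resolving the verdict classes.
#' @param frameIndex,timestamp Frame identification carried into the summary.
#' @param gazeOnPath Frame-level gaze-on-path flag; defaults to the
#'   `"gaze_on_path"` attribute left by [detectOverlaps()].
#' @return One-row data.frame with columns `frame_index`, `timestamp`,
#'   `n_detections`, `hazard_in_path`, `hazard_gazed`, `gaze_on_path`.
#' @export
summarizeFrame <- function(verdicts, taxonomy, frameIndex = NA_integer_,
                           timestamp = NA_real_,
                           gazeOnPath = attr(verdicts, "gaze_on_path")) {
  if (is.null(gazeOnPath)) gazeOnPath <- FALSE
  hazardInPath <- FALSE
  hazardGazed <- FALSE
  if (nrow(verdicts) > 0) {
    hz <- isHazardClass(taxonomy, verdicts$class)
    hazardInPath <- any(hz & verdicts$in_path)
    hazardGazed <- any(hz & verdicts$in_path & verdicts$gazed)
  }
  data.frame(frame_index = as.integer(frameIndex), timestamp = timestamp,
             n_detections = nrow(verdicts), hazard_in_path = hazardInPath,
             hazard_gazed = hazardGazed, gaze_on_path = gazeOnPath)
}

#' Contextualize a sequence of frames
#'
#' Runs [detectOverlaps()] and [summarizeFrame()] over a list of frames,
#' reusing the path mask across frames, and returns the flat per-detection
#' verdict table together with the per-frame context summary.
#'
#' @param frames List of [FrameRecord-class] objects with non-decreasing
#'   timestamps and identical dimensions.
#' @param taxonomy A [ClassTaxonomy-class].
#' @param path Optional [WalkingPath-class]; built with default geometry for
#'   the first frame's size when omitted.
#' @inheritParams detectOverlaps
#' @return `list(verdicts = <data.frame>, contexts = <data.frame>)`; the
#'   verdict table gains `frame_index` and `timestamp` columns.
#' @export
contextualizeFrames <- function(frames, taxonomy, path = NULL,
                                maskResolution = c(200, 200), gazeRadius = 30) {
  if (length(frames) == 0) stop("no frames supplied")
  ts <- vapply(frames, function(f) f@timestamp, numeric(1))
  if (is.unsorted(ts)) stop("frame timestamps must be non-decreasing")
  if (is.null(path)) {
    path <- buildWalkingPath(frames[[1L]]@width, frames[[1L]]@height)
  }
  pathMask <- rasterize(path, resolution = maskResolution)
  verdictList <- vector("list", length(frames))
  contextList <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    v <- detectOverlaps(fr, path, maskResolution, gazeRadius, pathMask = pathMask)
    contextList[[i]] <- summarizeFrame(v, taxonomy, fr@index, fr@timestamp)
    if (nrow(v) > 0) {
      v <- cbind(frame_index = fr@index, timestamp = fr@timestamp, v)
    }
    verdictList[[i]] <- v
  }
  verdictList <- verdictList[vapply(verdictList, nrow, integer(1)) > 0]
  verdicts <- if (length(verdictList)) {
    do.call(rbind, c(verdictList, list(make.row.names = FALSE)))
  } else {
    cbind(frame_index = integer(0), timestamp = numeric(0), emptyDetections(),
          in_path = logical(0), gazed = logical(0))
  }
  list(verdicts = verdicts,
       contexts = do.call(rbind, c(contextList, list(make.row.names = FALSE))))
}

#' Visual attention on in-path hazards over time windows
#'
#' Splits a time-ordered frame-context stream into fixed windows and, within
#' each window, reports the fraction of hazard-present frames (frames with a
#' fall-risk detection overlapping the walking path) in which an in-path
#' hazard was also gazed. Windows containing no hazard frames get an `NA`
#' fraction: attention on hazards is undefined when no hazard is present.
#'
#' @param contexts Frame-context data.frame from [contextualizeFrames()] /
#'   [summarizeFrame()] (columns `timestamp`, `hazard_in_path`,
#'   `hazard_gazed`), time-ordered.
#' @param window Window length in seconds (> 0).
#' @return data.frame with one row per window spanned by the stream:
#'   `window_start`, `window_end`, `n_frames`, `n_hazard_frames`,
#'   `attention_fraction`.
#' @export
attentionOnHazards <- function(contexts, window) {
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    stop("window must be a positive number of seconds")
  }
  if (is.unsorted(contexts$timestamp)) stop("contexts must be time-ordered")
  t0 <- contexts$timestamp[1L]
  idx <- floor((contexts$timestamp - t0) / window)
  windows <- sort(unique(idx))
  out <- lapply(windows, function(w) {
    sel <- contexts[idx == w, , drop = FALSE]
    hz <- sel$hazard_in_path
    data.frame(window_start = t0 + w * window,
               window_end = t0 + (w + 1) * window,
               n_frames = nrow(sel), n_hazard_frames = sum(hz),
               attention_fraction = if (any(hz)) mean(sel$hazard_gazed[hz]) else NA_real_)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
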