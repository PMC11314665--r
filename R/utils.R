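# Internal helpers shared across modules.

STANDARD_GRAVITY <- 9.80665  # m/s^2 per g

#' Run a function under a temporary RNG seed
#'
#' Evaluates `fun()` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so library calls never perturb
#' user-level reproducibility. With `seed = NULL` the function runs under the
#' current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param fun A zero-argument function.
#' @return The value of `fun()`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, fun) {
  if (is.null(seed)) {
    return(fun())
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fun()
}

# Bounding boxes are numeric length-4 vectors c(x_min, y_min, x_max, y_max) in
# 0-based, half-open pixel intervals [x_min, x_max) x [y_min, y_max).

assertBox <- function(box) {
  if (!is.numeric(box) || length(box) != 4L || anyNA(box)) {
    stop("a bounding box must be a numeric vector c(x_min, y_min, x_max, y_max)")
  }
  if (box[1L] >= box[3L] || box[2L] >= box[4L]) {
    stop("degenerate bounding box: x_min < x_max and y_min < y_max required")
  }
  invisible(box)
}

#' Clip a bounding box to a frame
#'
#' Boxes are 0-based half-open pixel intervals; the clipped box is the
#' intersection with `[0, width) x [0, height)`, or `NULL` when empty.
#'
#' @param box Numeric `c(x_min, y_min, x_max, y_max)`.
#' @param width,height Frame dimensions in pixels.
#' @return Clipped box, or `NULL` if the box lies outside the frame.
#' @export
#' @examples
#' clipBox(c(-10, -10, 50, 50), 40, 40)
clipBox <- function(box, width, height) {
  x0 <- max(box[1L], 0)
  y0 <- max(box[2L], 0)
  x1 <- min(box[3L], width)
  y1 <- min(box[4L], height)
  if (x0 >= x1 || y0 >= y1) {
    return(NULL)
  }
  c(x0, y0, x1, y1)
}

boxArea <- function(box) {
  (box[3L] - box[1L]) * (box[4L] - box[2L])
}

# Column template for detection / annotation tables.
emptyDetections <- function() {
  data.frame(
    class = character(0),
    x_min = numeric(0), y_min = numeric(0),
    x_max = numeric(0), y_max = numeric(0),
    confidence = numeric(0),
    stringsAsFactors = FALSE
  )
}

assertDetections <- function(detections) {
  needed <- c("class", "x_min", "y_min", "x_max", "y_max")
  if (!is.data.frame(detections) || !all(needed %in% names(detections))) {
    stop("detections must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  }
  if (nrow(detections) > 0) {
    bad <- detections$x_min >= detections$x_max |
      detections$y_min >= detections$y_max
    if (any(bad)) {
      stop("degenerate bounding box in detection row(s) ",
           paste(which(bad), collapse = ", "))
    }
  }
  invisible(detections)
}
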