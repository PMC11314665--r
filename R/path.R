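# Walking-path trapezoid geometry.

#' Build the trapezoidal walking-path model for a frame
#'
#' The immediate walking path is an isosceles trapezoid: its base sits on the
#' bottom row of the frame and spans, by default, the middle 50% of the frame
#' width (a logical, wide area directly in front of the wearer); the top edge
#' is narrower, representing the converging perspective of the forward view,
#' and sits at `topYFraction` of the frame height from the top.
#'
#' The base/top widths and top height are dimensionless fractions of the
#' frame size, so the same configuration applies to any camera resolution.
#'
#' @param frameWidth,frameHeight Frame dimensions in pixels (> 0).
#' @param baseWidthFraction Base width as a fraction of frame width,
#'   default 0.5.
#' @param topWidthFraction Top width as a fraction of frame width, default
#'   0.15; must not exceed `baseWidthFraction`.
#' @param topYFraction Vertical position of the top edge as a fraction of the
#'   frame height from the top, default 0.55.
#' @return A [WalkingPath-class].
#' @export
#' @examples
#' p <- buildWalkingPath(1000, 800)
#' pathVertices(p)   # base from x = 250 to x = 750 on the bottom row
buildWalkingPath <- function(frameWidth, frameHeight,
                             baseWidthFraction = 0.5,
                             topWidthFraction = 0.15,
                             topYFraction = 0.55) {
  if (frameWidth <= 0 || frameHeight <= 0) stop("frame dimensions must be positive")
  if (baseWidthFraction <= 0 || baseWidthFraction > 1 ||
      topWidthFraction <= 0 || topWidthFraction > 1) {
    stop("width fractions must lie in (0, 1]")
  }
  if (topYFraction < 0 || topYFraction >= 1) stop("topYFraction must lie in [0, 1)")
  if (topWidthFraction > baseWidthFraction) {
    stop("top edge wider than base: perspective must converge")
  }
  baseW <- round(baseWidthFraction * frameWidth)
  topW <- round(topWidthFraction * frameWidth)
  topY <- round(topYFraction * frameHeight)
  cx <- frameWidth / 2
  vertices <- rbind(
    c(cx - baseW / 2, frameHeight),  # bottom-left
    c(cx + baseW / 2, frameHeight),  # bottom-right
    c(cx + topW / 2, topY),          # top-right
    c(cx - topW / 2, topY)           # top-left
  )
  colnames(vertices) <- c("x", "y")
  new("WalkingPath", vertices = vertices,
      frameWidth = as.numeric(frameWidth), frameHeight = as.numeric(frameHeight))
}

# Horizontal extent [xl, xr] of the trapezoid at depth y (clamped to the
# trapezoid's vertical span). The extent widens monotonically towards the
# frame bottom, which rasterization and the per-pixel oracle both exploit.
pathXRange <- function(path, y) {
  v <- path@vertices
  topY <- v[4, 2]
  botY <- v[1, 2]
  frac <- if (botY > topY) (y - topY) / (botY - topY) else 1
  frac <- min(max(frac, 0), 1)
  c(v[4, 1] + frac * (v[1, 1] - v[4, 1]),
    v[3, 1] + frac * (v[2, 1] - v[3, 1]))
}

# Does an axis-aligned box (half-open pixel interval) intersect the (closed)
# trapezoid? Exact continuous-geometry test: the trapezoid's x-extent is
# nested/increasing with y, so it suffices to test at the deepest y the box
# reaches inside the trapezoid's vertical span.
boxIntersectsPath <- function(box, path) {
  v <- path@vertices
  topY <- v[4, 2]
  botY <- v[1, 2]
  yDeep <- min(box[4L], botY)
  if (yDeep <= max(box[2L], topY)) return(FALSE)
  xr <- pathXRange(path, yDeep)
  box[1L] < xr[2L] && box[3L] > xr[1L]
}

# Does a point lie inside the (closed) trapezoid?
pointInPath <- function(x, y, path) {
  v <- path@vertices
  if (y < v[4, 2] || y > v[1, 2]) return(FALSE)
  xr <- pathXRange(path, y)
  x >= xr[1L] && x <= xr[2L]
}
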