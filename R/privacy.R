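# Selective anonymization: Gaussian blur of privacy-role detection ROIs,
# leaving every other pixel bit-identical.

#' @describeIn blurSensitive default Gaussian standard deviation for a given
#'   odd kernel size: `0.3 * ((k - 1) * 0.5 - 1) + 0.8` (the common automatic
#'   convention used by image-processing toolkits).
#' @export
autoSigma <- function(kernelSize) {
  0.3 * ((kernelSize - 1) * 0.5 - 1) + 0.8
}

gaussianKernel1d <- function(kernelSize, sigma) {
  half <- (kernelSize - 1) / 2
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Reflect-101 padding indices: positions (1 - pad):(n + pad) folded into
# 1..n by mirroring about the edge samples (no edge duplication). Handles
# pad larger than n by periodic folding; a length-1 axis maps to itself.
reflectIndex <- function(n, pad) {
  p <- seq.int(1 - pad, n + pad)
  if (n == 1) return(rep(1L, length(p)))
  m <- abs(p - 1) %% (2 * n - 2)
  as.integer(ifelse(m < n, m + 1, 2 * n - 1 - m))
}

# Separable Gaussian blur of a numeric matrix with reflect-101 borders,
# computed as banded-matrix products (exact direct convolution, no FFT).
blurMatrix <- function(X, kernelSize, sigma) {
  g <- gaussianKernel1d(kernelSize, sigma)
  pad <- (kernelSize - 1) / 2
  convAxis <- function(n) {
    K <- matrix(0, nrow = n, ncol = n + 2 * pad)
    for (i in seq_len(n)) K[i, i:(i + kernelSize - 1)] <- g
    K
  }
  n <- nrow(X)
  m <- ncol(X)
  Kr <- convAxis(n)
  Y <- Kr %*% X[reflectIndex(n, pad), , drop = FALSE]
  Kc <- convAxis(m)
  Y[, reflectIndex(m, pad), drop = FALSE] %*% t(Kc)
}

assertFrameImage <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L ||
      any(dim(image)[1:2] < 1L)) {
    stop("a frame image must be a non-empty height x width x 3 array")
  }
  invisible(image)
}

#' Blur privacy-sensitive regions of a frame
#'
#' Applies a Gaussian blur to the region of interest (ROI) of every
#' privacy-role detection (e.g. `Person`, `Screen`, `Book` in the built-in
#' taxonomy), replacing each ROI by its blurred version while leaving all
#' pixels outside the union of privacy ROIs bit-identical to the input. The
#' blur is computed on the ROI crop in isolation with reflect-101 border
#' handling, so no information leaks across the ROI boundary in either
#' direction. Overlapping ROIs are blurred sequentially in detection order;
#' their intersection ends up blurred either way.
#'
#' All detections count regardless of confidence: privacy errs toward
#' over-obscuring.
#'
#' @param image 8-bit frame as a `height x width x 3` array of intensities
#'   in 0..255 (see [readFrameImage()]).
#' @param detections Detection data.frame (`class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`); boxes are clipped to the frame.
#' @param taxonomy A [ClassTaxonomy-class] declaring which classes carry the
#'   privacy role.
#' @param kernelSize Odd Gaussian kernel size >= 3, default 157.
#' @param sigma Gaussian standard deviation in pixels; defaults to
#'   [autoSigma()] of the kernel size.
#' @return The anonymized image array, with the number of blurred regions
#'   attached as attribute `"n_blurred"`.
#' @export
#' @examples
#' img <- array(rep(seq(0, 255, length.out = 64), 3), c(8, 8, 3))
#' tax <- loadTaxonomy()
#' det <- data.frame(class = "Person", x_min = 2, y_min = 2, x_max = 6,
#'                   y_max = 6, confidence = 0.9)
#' out <- blurSensitive(img, det, tax, kernelSize = 5)
blurSensitive <- function(image, detections, taxonomy, kernelSize = 157,
                          sigma = autoSigma(kernelSize)) {
  assertFrameImage(image)
  if (kernelSize < 3 || kernelSize %% 2 == 0) {
    stop("kernelSize must be an odd integer >= 3")
  }
  assertDetections(detections)
  H <- dim(image)[1L]
  W <- dim(image)[2L]
  nBlurred <- 0L
  if (nrow(detections) > 0) {
    priv <- isPrivacyClass(taxonomy, detections$class)
    for (k in which(priv)) {
      box <- clipBox(as.numeric(detections[k, c("x_min", "y_min", "x_max", "y_max")]),
                     W, H)
      if (is.null(box)) next
      rows <- (floor(box[2L]) + 1L):ceiling(box[4L])
      cols <- (floor(box[1L]) + 1L):ceiling(box[3L])
      for (ch in 1:3) {
        roi <- image[rows, cols, ch, drop = TRUE]
        if (!is.matrix(roi)) roi <- matrix(roi, nrow = length(rows))
        blurred <- blurMatrix(roi, kernelSize, sigma)
        # round back to 8-bit; integer storage keeps untouched pixels bit-identical
        image[rows, cols, ch] <- as.integer(pmin(pmax(round(blurred), 0), 255))
      }
      nBlurred <- nBlurred + 1L
    }
  }
  attr(image, "n_blurred") <- nBlurred
  image
}

#' Anonymize a frame sequence
#'
#' Applies [blurSensitive()] to every frame of a sequence with its matching
#' per-frame detections, and reports the total number of blurred regions
#' (one per privacy-role detection).
#'
#' @param images List of frame image arrays.
#' @param detectionsList List of detection data.frames, one per frame (same
#'   length as `images`).
#' @inheritParams blurSensitive
#' @return `list(images = <anonymized frames>, nBlurred = <count>)`.
#' @export
processStream <- function(images, detectionsList, taxonomy, kernelSize = 157,
                          sigma = autoSigma(kernelSize)) {
  if (length(images) != length(detectionsList)) {
    stop("frame count (", length(images), ") and detection-record count (",
         length(detectionsList), ") differ")
  }
  total <- 0L
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    blurred <- blurSensitive(images[[i]], detectionsList[[i]], taxonomy,
                             kernelSize, sigma)
    total <- total + attr(blurred, "n_blurred")
    attr(blurred, "n_blurred") <- NULL
    out[[i]] <- blurred
  }
  list(images = out, nBlurred = total)
}

#' Read and write 8-bit frame images
#'
#' Frames are handled as `height x width x 3` arrays of integer intensities
#' in 0..255. `readFrameImage()` reads a PNG (grayscale and alpha channels
#' are expanded/dropped to RGB); `writeFrameImage()` writes one. Audio is
#' never ingested or emitted by any part of the pipeline.
#'
#' @param path PNG file path.
#' @param image Frame array as returned by [readFrameImage()].
#' @return `readFrameImage()` returns the frame array; `writeFrameImage()`
#'   returns `path` invisibly.
#' @export
readFrameImage <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3L] > 3L) x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim = dim(x))
}

#' @rdname readFrameImage
#' @export
writeFrameImage <- function(image, path) {
  assertFrameImage(image)
  png::writePNG(image / 255, path)
  invisible(path)
}
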