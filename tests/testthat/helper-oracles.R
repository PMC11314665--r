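# Independent oracles used across tests. These deliberately re-derive
# results from first principles (brute-force loops, continuous geometry,
# direct convolution) and never call the implementation paths they check.

# Brute-force mask oracle: cell set iff its full-frame footprint rectangle
# intersects the box (closed/half-open handled explicitly).
bruteBoxMask <- function(box, W, H, wm, hm) {
  bits <- matrix(FALSE, hm, wm)
  for (i in seq_len(hm)) {
    y0 <- (i - 1) * H / hm; y1 <- i * H / hm
    for (j in seq_len(wm)) {
      x0 <- (j - 1) * W / wm; x1 <- j * W / wm
      bits[i, j] <- x0 < box[3] && x1 > box[1] && y0 < box[4] && y1 > box[2]
    }
  }
  bits
}

# Brute-force circle mask oracle: closed footprint rectangle vs disk.
bruteCircleMask <- function(cx, cy, r, W, H, wm, hm) {
  bits <- matrix(FALSE, hm, wm)
  for (i in seq_len(hm)) {
    y0 <- (i - 1) * H / hm; y1 <- i * H / hm
    for (j in seq_len(wm)) {
      x0 <- (j - 1) * W / wm; x1 <- j * W / wm
      dx <- max(0, x0 - cx, cx - x1)
      dy <- max(0, y0 - cy, cy - y1)
      bits[i, j] <- dx^2 + dy^2 <= r^2
    }
  }
  bits
}

# Trapezoid helpers on vertex matrices (independent of pathXRange()).
trapezoidXAt <- function(vertices, y) {
  topY <- vertices[4, 2]; botY <- vertices[1, 2]
  f <- if (botY > topY) min(max((y - topY) / (botY - topY), 0), 1) else 1
  c(vertices[4, 1] + f * (vertices[1, 1] - vertices[4, 1]),
    vertices[3, 1] + f * (vertices[2, 1] - vertices[3, 1]))
}

# Per-pixel oracle for one frame: full-resolution membership grids, from
# which box/path and box/gaze overlap verdicts are derived by brute force.
# Pixels are unit squares [p, p+1) x [q, q+1).
pixelOracleVerdicts <- function(frame, vertices, gazeRadius) {
  W <- frame@width; H <- frame@height
  pathPix <- matrix(FALSE, H, W)
  for (q in seq_len(H)) {
    y0 <- q - 1; y1 <- q
    topY <- vertices[4, 2]
    if (y1 <= topY) next
    xr <- trapezoidXAt(vertices, min(y1, vertices[1, 2]))
    cols <- which((seq_len(W) - 1) < xr[2] & seq_len(W) > xr[1])
    if (length(cols)) pathPix[q, cols] <- TRUE
  }
  gazePix <- NULL
  if (frame@gazeValid) {
    gazePix <- bruteCircleMask(frame@gazeX, frame@gazeY, gazeRadius, W, H, W, H)
  }
  det <- frameDetections(frame)
  t(vapply(seq_len(nrow(det)), function(k) {
    b <- pmax(pmin(as.numeric(det[k, c("x_min", "y_min", "x_max", "y_max")]),
                   c(W, H, W, H)), 0)
    if (b[1] >= b[3] || b[2] >= b[4]) return(c(FALSE, FALSE))
    rows <- (floor(b[2]) + 1):ceiling(b[4])
    cols <- (floor(b[1]) + 1):ceiling(b[3])
    c(any(pathPix[rows, cols]),
      if (is.null(gazePix)) FALSE else any(gazePix[rows, cols]))
  }, logical(2)))
}

# Direct double-loop separable-Gaussian convolution with reflect-101
# borders; the oracle for blurSensitive() on small crops.
directBlurOracle <- function(img, kernelSize, sigma) {
  half <- (kernelSize - 1) / 2
  g1 <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  K2 <- outer(g1, g1)
  refl <- function(i, n) {
    m <- abs(i - 1) %% (2 * n - 2)
    ifelse(m < n, m + 1, 2 * n - 1 - m)
  }
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- array(0L, dim(img))
  for (ch in seq_len(dim(img)[3])) {
    for (y in seq_len(H)) for (x in seq_len(W)) {
      acc <- 0
      for (dy in seq(-half, half)) for (dx in seq(-half, half)) {
        acc <- acc + K2[dy + half + 1, dx + half + 1] *
          img[refl(y + dy, H), refl(x + dx, W), ch]
      }
      out[y, x, ch] <- as.integer(min(max(round(acc), 0), 255))
    }
  }
  out
}

randomNoiseImage <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(as.integer(round(stats::runif(h * w * 3) * 255)), c(h, w, 3))
}
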