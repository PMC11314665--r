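tax <- loadTaxonomy()

test_that("frames without privacy detections pass through bit-identical", {
  img <- randomNoiseImage(30, 40, seed = 1)
  det <- data.frame(class = c("Chair", "Stairs"), x_min = c(2, 20),
                    y_min = c(2, 5), x_max = c(15, 35), y_max = c(15, 25),
                    confidence = 0.9)
  out <- blurSensitive(img, det, tax, kernelSize = 15)
  expect_equal(attr(out, "n_blurred"), 0L)
  attr(out, "n_blurred") <- NULL
  expect_identical(out, img)
})

test_that("blur touches only privacy ROIs and leaves them obscured", {
  img <- randomNoiseImage(60, 80, seed = 2)
  det <- data.frame(class = "Person", x_min = 10, y_min = 12, x_max = 50,
                    y_max = 48, confidence = 0.7)
  out <- blurSensitive(img, det, tax, kernelSize = 21)
  rows <- 13:48; cols <- 11:50
  for (ch in 1:3) {
    inside <- img[rows, cols, ch]
    # everything outside the ROI is bit-identical
    patched <- out
    patched[rows, cols, ] <- img[rows, cols, ]
    expect_identical(patched[, , ch], img[, , ch])
    # inside the ROI variance strictly decreases per channel
    expect_lt(var(as.numeric(out[rows, cols, ch])), var(as.numeric(inside)))
  }
  # a constant-colour ROI is unchanged (Gaussian of a constant)
  flat <- img
  flat[rows, cols, ] <- 123L
  outFlat <- blurSensitive(flat, det, tax, kernelSize = 21)
  attr(outFlat, "n_blurred") <- NULL
  expect_identical(outFlat, flat)
})

test_that("blur matches a direct convolution oracle within one level", {
  img <- randomNoiseImage(32, 32, seed = 3)
  det <- data.frame(class = "Screen", x_min = 0, y_min = 0, x_max = 32,
                    y_max = 32, confidence = 1)
  k <- 9
  out <- blurSensitive(img, det, tax, kernelSize = k)
  oracle <- directBlurOracle(img, k, autoSigma(k))
  expect_lte(max(abs(out - oracle)), 1L)
})

test_that("re-blurring changes pixels less than the first blur did", {
  img <- randomNoiseImage(40, 40, seed = 4)
  det <- data.frame(class = "Book", x_min = 4, y_min = 4, x_max = 36,
                    y_max = 36, confidence = 1)
  once <- blurSensitive(img, det, tax, kernelSize = 13)
  twice <- blurSensitive(once, det, tax, kernelSize = 13)
  d1 <- mean(abs(as.numeric(once) - as.numeric(img)))
  d2 <- mean(abs(as.numeric(twice) - as.numeric(once)))
  expect_lt(d2, d1)
})

test_that("overlapping privacy ROIs both end up blurred", {
  img <- randomNoiseImage(50, 50, seed = 5)
  det <- data.frame(class = c("Person", "Screen"),
                    x_min = c(5, 20), y_min = c(5, 20),
                    x_max = c(35, 45), y_max = c(35, 45), confidence = 1)
  out <- blurSensitive(img, det, tax, kernelSize = 17)
  expect_equal(attr(out, "n_blurred"), 2L)
  inter <- list(rows = 21:35, cols = 21:35)
  expect_lt(var(as.numeric(out[inter$rows, inter$cols, 1])),
            var(as.numeric(img[inter$rows, inter$cols, 1])))
})

test_that("kernel and image preconditions are enforced", {
  img <- randomNoiseImage(10, 10, seed = 6)
  det <- data.frame(class = "Person", x_min = 1, y_min = 1, x_max = 9,
                    y_max = 9, confidence = 1)
  expect_error(blurSensitive(img, det, tax, kernelSize = 16), "odd")
  expect_error(blurSensitive(img, det, tax, kernelSize = 1), "odd")
  expect_error(blurSensitive(array(0L, c(0, 4, 3)), det, tax), "non-empty")
})

test_that("stream processing counts one blur per privacy detection", {
  imgs <- lapply(1:3, function(i) randomNoiseImage(24, 24, seed = 10 + i))
  person <- data.frame(class = "Person", x_min = 2, y_min = 2, x_max = 20,
                       y_max = 20, confidence = 1)
  # zero privacy detections -> zero regions
  none <- lapply(1:3, function(i) person[0, ])
  expect_equal(processStream(imgs, none, tax, kernelSize = 9)$nBlurred, 0L)
  # one Person per frame -> 3 regions
  expect_equal(processStream(imgs, list(person, person, person), tax,
                             kernelSize = 9)$nBlurred, 3L)
  # Person + Screen + Chair in one frame -> 2 regions (Chair is not privacy)
  mixed <- data.frame(class = c("Person", "Screen", "Chair"),
                      x_min = c(1, 8, 14), y_min = c(1, 8, 14),
                      x_max = c(7, 13, 22), y_max = c(7, 13, 22),
                      confidence = 1)
  expect_equal(processStream(imgs[1], list(mixed), tax, kernelSize = 9)$nBlurred, 2L)
  expect_error(processStream(imgs, list(person), tax), "differ")
})
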