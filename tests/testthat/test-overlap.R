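makeFrame <- function(det, gazeX = NA, gazeY = NA, W = 640, H = 480, ts = 0) {
  FrameRecord(0, ts, W, H, det, gazeX = gazeX, gazeY = gazeY)
}

chairBox <- function(x0, y0, x1, y1, class = "Chair") {
  data.frame(class = class, x_min = x0, y_min = y0, x_max = x1, y_max = y1,
             confidence = 0.9, stringsAsFactors = FALSE)
}

test_that("clearly disjoint and clearly contained cases verdict correctly", {
  path <- buildWalkingPath(640, 480)
  # box in the top-left corner, far from path and gaze
  fr <- makeFrame(chairBox(5, 5, 80, 80), gazeX = 600, gazeY = 400)
  v <- detectOverlaps(fr, path)
  expect_false(v$in_path)
  expect_false(v$gazed)
  # box straddling the path base with the gaze centred inside it
  fr2 <- makeFrame(chairBox(280, 380, 420, 475), gazeX = 350, gazeY = 420)
  v2 <- detectOverlaps(fr2, path)
  expect_true(v2$in_path)
  expect_true(v2$gazed)
  expect_true(attr(v2, "gaze_on_path"))
})

test_that("missing or invalid gaze yields gazed = FALSE, not an error", {
  path <- buildWalkingPath(640, 480)
  fr <- makeFrame(chairBox(280, 380, 420, 475))
  v <- detectOverlaps(fr, path)
  expect_true(v$in_path)
  expect_false(v$gazed)
  expect_false(attr(v, "gaze_on_path"))
})

test_that("verdicts are invariant to detection order and empty input works", {
  path <- buildWalkingPath(640, 480)
  det <- rbind(chairBox(280, 380, 420, 475),
               chairBox(5, 5, 60, 60, "Person"),
               chairBox(500, 300, 620, 460, "Obstacle"))
  v1 <- detectOverlaps(makeFrame(det, 350, 420), path)
  v2 <- detectOverlaps(makeFrame(det[3:1, ], 350, 420), path)
  key <- function(v) v[order(v$x_min), c("in_path", "gazed")]
  expect_equal(key(v1), key(v2), ignore_attr = TRUE)
  v0 <- detectOverlaps(makeFrame(chairBox(1, 1, 2, 2)[0, ]), path)
  expect_equal(nrow(v0), 0L)
})

test_that("at full mask resolution verdicts equal the per-pixel oracle", {
  W <- 64; H <- 50
  path <- buildWalkingPath(W, H)
  set.seed(7)
  for (rep in 1:20) {
    det <- do.call(rbind, lapply(1:3, function(k) {
      x0 <- sample(0:(W - 6), 1); y0 <- sample(0:(H - 6), 1)
      chairBox(x0, y0, x0 + sample(4:20, 1), y0 + sample(4:20, 1))
    }))
    det$x_max <- pmin(det$x_max, W); det$y_max <- pmin(det$y_max, H)
    fr <- makeFrame(det, gazeX = runif(1, 0, W - 1), gazeY = runif(1, 0, H - 1),
                    W = W, H = H)
    v <- detectOverlaps(fr, path, maskResolution = c(W, H), gazeRadius = 6)
    oracle <- pixelOracleVerdicts(fr, pathVertices(path), gazeRadius = 6)
    expect_equal(v$in_path, oracle[, 1])
    expect_equal(v$gazed, oracle[, 2])
  }
})

test_that("frame summaries flag hazards by role, not by mere presence", {
  tax <- loadTaxonomy()
  path <- buildWalkingPath(640, 480)
  # context-only class in the path does not raise the hazard flag
  v <- detectOverlaps(makeFrame(chairBox(280, 380, 420, 475, "Bed")), path)
  s <- summarizeFrame(v, tax, 0, 0)
  expect_false(s$hazard_in_path)
  # a hazard-role class in the path does
  v2 <- detectOverlaps(makeFrame(chairBox(280, 380, 420, 475, "Raised kerb")), path)
  s2 <- summarizeFrame(v2, tax, 0, 0)
  expect_true(s2$hazard_in_path)
  # no detections at all
  s0 <- summarizeFrame(detectOverlaps(makeFrame(chairBox(1, 1, 2, 2)[0, ]), path),
                       tax, 0, 0)
  expect_false(s0$hazard_in_path)
  expect_error(summarizeFrame(transform(v2, class = "Gremlin"), tax),
               "not in taxonomy")
})

test_that("attention windows report the gazed fraction of hazard frames", {
  ctx <- function(ts, hz, gz) {
    data.frame(timestamp = ts, hazard_in_path = hz, hazard_gazed = gz)
  }
  # hazard present throughout, never gazed -> 0
  a <- attentionOnHazards(ctx(0:9, TRUE, FALSE), window = 10)
  expect_equal(a$attention_fraction, 0)
  # gazed in every hazard frame -> 1
  b <- attentionOnHazards(ctx(0:9, TRUE, TRUE), window = 10)
  expect_equal(b$attention_fraction, 1)
  # alternating gazed/not over 10 hazard frames -> 0.5
  cc <- attentionOnHazards(ctx(0:9, TRUE, rep(c(TRUE, FALSE), 5)), window = 10)
  expect_equal(cc$attention_fraction, 0.5)
  # windows without hazard frames are undefined (NA)
  d <- attentionOnHazards(ctx(0:19, rep(c(TRUE, FALSE), each = 10), FALSE),
                          window = 10)
  expect_equal(d$attention_fraction, c(0, NA))
  expect_error(attentionOnHazards(ctx(0, TRUE, TRUE), window = 0), "positive")
})
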