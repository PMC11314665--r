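tax <- loadTaxonomy()

test_that("yolo annotations convert to half-open pixel boxes", {
  f <- tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 1.0 1.0", f)
  det <- readAnnotations(f, "yolo_txt", 200, 100, tax)
  expect_equal(as.numeric(det[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(0, 0, 200, 100))
  expect_equal(det$class, classNames(tax)[1])

  writeLines("2 0.25 0.25 0.5 0.5", f)
  det2 <- readAnnotations(f, "yolo_txt", 400, 400, tax)
  expect_equal(as.numeric(det2[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(0, 0, 200, 200))

  writeLines("0 1.5 0.5 1.0 1.0", f)
  expect_error(readAnnotations(f, "yolo_txt", 200, 100, tax), "outside")
  writeLines("99 0.5 0.5 0.2 0.2", f)
  expect_error(readAnnotations(f, "yolo_txt", 200, 100, tax), "unknown class id")
})

test_that("voc xml parses corner pixels and rejects inverted boxes", {
  f <- tempfile(fileext = ".xml")
  writeLines(c("<annotation><object><name>Chair</name><bndbox>",
               "<xmin>11</xmin><ymin>21</ymin><xmax>110</xmax><ymax>120</ymax>",
               "</bndbox></object></annotation>"), f)
  det <- readAnnotations(f, "voc_xml", taxonomy = tax)
  expect_equal(as.numeric(det[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(10, 20, 110, 120))
  writeLines(c("<annotation><object><name>Chair</name><bndbox>",
               "<xmin>110</xmin><ymin>21</ymin><xmax>11</xmax><ymax>120</ymax>",
               "</bndbox></object></annotation>"), f)
  expect_error(readAnnotations(f, "voc_xml", taxonomy = tax), "max < min")
})

test_that("yolo write/read round-trips boxes within one pixel", {
  set.seed(8)
  W <- 1088; H <- 1080
  det <- data.frame(class = sample(classNames(tax), 20, replace = TRUE),
                    x_min = numeric(20), y_min = numeric(20),
                    x_max = numeric(20), y_max = numeric(20),
                    confidence = NA_real_)
  for (i in 1:20) {
    x <- sort(sample(0:W, 2)); y <- sort(sample(0:H, 2))
    det[i, 2:5] <- c(x[1], y[1], max(x[2], x[1] + 5), max(y[2], y[1] + 5))
  }
  f <- tempfile(fileext = ".txt")
  writeAnnotations(det, f, W, H, tax)
  again <- readAnnotations(f, "yolo_txt", W, H, tax)
  expect_equal(again$class, det$class)
  for (col in c("x_min", "y_min", "x_max", "y_max")) {
    expect_lte(max(abs(again[[col]] - det[[col]])), 1)
  }
})

test_that("dataset split is deterministic, disjoint and exhaustive", {
  s <- splitDataset(letters[1:10], 0.8, seed = 1)
  expect_length(s$train, 8L)
  expect_length(s$validation, 2L)
  expect_setequal(c(s$train, s$validation), letters[1:10])
  expect_length(intersect(s$train, s$validation), 0L)
  expect_identical(s, splitDataset(letters[1:10], 0.8, seed = 1))
  expect_false(identical(s, splitDataset(letters[1:10], 0.8, seed = 2)))
  one <- splitDataset("a", 0.8, seed = 1)
  expect_length(one$train, 1L)
  expect_length(one$validation, 0L)
  expect_error(splitDataset(character(0)), "empty")
  expect_error(splitDataset(letters, ratio = 1), "ratio")
})

test_that("iou obeys its identities and the hand-computed case", {
  a <- c(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(20, 20, 30, 30)), 0)
  expect_equal(iou(a, c(5, 0, 15, 10)), 1 / 3)
  set.seed(9)
  for (rep in 1:20) {
    b1 <- c(sort(runif(2, 0, 100)), sort(runif(2, 0, 100)))[c(1, 3, 2, 4)] + c(0, 0, 1, 1)
    b2 <- c(sort(runif(2, 0, 100)), sort(runif(2, 0, 100)))[c(1, 3, 2, 4)] + c(0, 0, 1, 1)
    v <- iou(b1, b2)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, iou(b2, b1))
  }
})

test_that("mAP50 handles the perfect, empty and hand-enumerated cases", {
  truth <- data.frame(image_id = rep("f0", 2), class = "Chair",
                      x_min = c(0, 20), y_min = 0, x_max = c(10, 30), y_max = 10)
  perfect <- cbind(truth, confidence = 1)
  expect_equal(evaluateMap50(perfect, truth)$map50, 1)
  expect_equal(evaluateMap50(perfect[0, ], truth)$map50, 0)
  # 2 truth boxes; one correct prediction (conf .9), one disjoint FP (conf .8)
  pred <- data.frame(image_id = "f0", class = "Chair",
                     x_min = c(0, 50), y_min = 0, x_max = c(10, 60), y_max = 10,
                     confidence = c(0.9, 0.8))
  expect_equal(evaluateMap50(pred, truth)$map50, 0.5)
  expect_equal(evaluateMap50(pred, truth, interpolation = "11point")$map50,
               6 / 11)
  expect_error(evaluateMap50(transform(pred, confidence = NA), truth),
               "confidence")
})

test_that("mAP50 is order-invariant and duplicates cannot raise AP", {
  set.seed(10)
  truth <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(image_id = paste0("f", i), class = sample(c("Chair", "Person"), 2, TRUE),
               x_min = c(0, 40), y_min = c(0, 40), x_max = c(20, 60),
               y_max = c(20, 60))
  }))
  pred <- transform(truth, confidence = runif(nrow(truth), 0.3, 1))
  pred$x_min <- pred$x_min + sample(0:6, nrow(pred), TRUE)   # jitter, still >= 0.5 IoU
  base <- evaluateMap50(pred, truth)$map50
  shuffled <- evaluateMap50(pred[sample(nrow(pred)), ], truth)$map50
  expect_equal(base, shuffled)
  dup <- rbind(pred, transform(pred[1, ], confidence = confidence - 0.01))
  expect_lte(evaluateMap50(dup, truth)$map50, base)
})

test_that("mAP50 averages only over classes present in the truth", {
  truth <- data.frame(image_id = "f0", class = "Chair",
                      x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  pred <- data.frame(image_id = "f0", class = c("Chair", "Person"),
                     x_min = c(0, 30), y_min = c(0, 30), x_max = c(10, 40),
                     y_max = c(10, 40), confidence = 1)
  res <- evaluateMap50(pred, truth)
  expect_named(res$perClass, "Chair")
  expect_equal(res$map50, 1)
})

test_that("the replay backend serves stored annotations as detections", {
  rec <- data.frame(class = "Chair", x_min = 0, y_min = 0, x_max = 5,
                    y_max = 5, confidence = NA_real_)
  backend <- makeReplayBackend(list(img1 = rec))
  out <- backend("img1")
  expect_equal(out$confidence, 1.0)
  expect_equal(nrow(backend("unseen")), 0L)
})
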