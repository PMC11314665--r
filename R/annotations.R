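# Annotation and detection I/O (YOLO text, Pascal VOC XML), dataset split,
# and a replay detector backend.

#' Read object annotations
#'
#' Reads one image's annotations from either YOLO text format (lines
#' `class_id cx cy w h [confidence]` with centre/size normalized to
#' `[0, 1]`) or Pascal VOC XML (1-based inclusive corner pixels, as written
#' by LabelImg). Boxes are converted to the package convention of 0-based,
#' half-open pixel intervals.
#'
#' @param path Annotation file.
#' @param format `"yolo_txt"` or `"voc_xml"`.
#' @param imageWidth,imageHeight Image dimensions in pixels; required for
#'   YOLO input, read from the `<size>` element for VOC when omitted.
#' @param taxonomy A [ClassTaxonomy-class] mapping YOLO class ids (0-based
#'   taxonomy order) to names and validating VOC names.
#' @return Detection data.frame (`class`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `confidence`; `NA` confidence for ground truth) with the image
#'   id (file base name) attached as attribute `"image_id"`.
#' @export
readAnnotations <- function(path, format = c("yolo_txt", "voc_xml"),
                            imageWidth = NULL, imageHeight = NULL,
                            taxonomy = loadTaxonomy()) {
  format <- match.arg(format)
  out <- if (format == "yolo_txt") {
    if (is.null(imageWidth) || is.null(imageHeight)) {
      stop("image dimensions are required for yolo_txt input")
    }
    readYoloTxt(path, imageWidth, imageHeight, taxonomy)
  } else {
    readVocXml(path, taxonomy)
  }
  attr(out, "image_id") <- sub("\\.[^.]*$", "", basename(path))
  out
}

readYoloTxt <- function(path, W, H, taxonomy) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(emptyDetections())
  rows <- lapply(seq_along(lines), function(i) {
    f <- as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]])
    if (length(f) < 5 || length(f) > 6 || anyNA(f)) {
      stop("malformed yolo line ", i, " in ", path)
    }
    id <- f[1L]
    if (id != floor(id) || id < 0 || id >= length(taxonomy)) {
      stop("unknown class id ", id, " on line ", i, " of ", path)
    }
    if (any(f[2:5] < 0) || any(f[2:5] > 1)) {
      stop("normalized value outside [0, 1] on line ", i, " of ", path)
    }
    data.frame(class = classNames(taxonomy)[id + 1L],
               x_min = round((f[2L] - f[4L] / 2) * W),
               y_min = round((f[3L] - f[5L] / 2) * H),
               x_max = round((f[2L] + f[4L] / 2) * W),
               y_max = round((f[3L] + f[5L] / 2) * H),
               confidence = if (length(f) == 6) f[6L] else NA_real_,
               stringsAsFactors = FALSE)
  })
  det <- do.call(rbind, rows)
  det$x_max <- pmin(det$x_max, W)
  det$y_max <- pmin(det$y_max, H)
  det$x_min <- pmax(det$x_min, 0)
  det$y_min <- pmax(det$y_min, 0)
  assertDetections(det)
}

readVocXml <- function(path, taxonomy) {
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0) return(emptyDetections())
  rows <- lapply(objs, function(o) {
    name <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    resolveClass(taxonomy, name)  # errors on unknown class names
    num <- function(tag) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", tag))))
    }
    xmin <- num("xmin"); ymin <- num("ymin")
    xmax <- num("xmax"); ymax <- num("ymax")
    if (anyNA(c(xmin, ymin, xmax, ymax))) stop("malformed bndbox in ", path)
    if (xmax < xmin || ymax < ymin) {
      stop("invalid box (max < min) for object '", name, "' in ", path)
    }
    conf <- xml2::xml_find_first(o, "./confidence")
    data.frame(class = name,
               x_min = xmin - 1, y_min = ymin - 1, x_max = xmax, y_max = ymax,
               confidence = if (inherits(conf, "xml_missing")) NA_real_
                            else as.numeric(xml2::xml_text(conf)),
               stringsAsFactors = FALSE)
  })
  assertDetections(do.call(rbind, rows))
}

#' Write annotations in YOLO text format
#'
#' Inverse of [readAnnotations()] for `format = "yolo_txt"`; centre/size
#' values are written normalized with 6 significant decimals, so a
#' write/read round trip reproduces boxes within 1 pixel.
#'
#' @param detections Detection data.frame.
#' @param path Output file.
#' @param imageWidth,imageHeight Image dimensions in pixels.
#' @param taxonomy A [ClassTaxonomy-class] (class ids are 0-based taxonomy
#'   positions).
#' @param writeConfidence Append the confidence column when present.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(detections, path, imageWidth, imageHeight,
                             taxonomy = loadTaxonomy(), writeConfidence = FALSE) {
  assertDetections(detections)
  ids <- resolveClass(taxonomy, detections$class) - 1L
  cx <- (detections$x_min + detections$x_max) / 2 / imageWidth
  cy <- (detections$y_min + detections$y_max) / 2 / imageHeight
  w <- (detections$x_max - detections$x_min) / imageWidth
  h <- (detections$y_max - detections$y_min) / imageHeight
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", ids, cx, cy, w, h)
  if (writeConfidence && "confidence" %in% names(detections)) {
    lines <- sprintf("%s %.6f", lines, detections$confidence)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic train/validation split
#'
#' Randomly partitions items into a training and a validation set with a
#' fixed seed, as used for detector fine-tuning datasets (default 80:20).
#' The partition is disjoint, exhaustive and reproducible: the same seed
#' always yields the same split.
#'
#' @param items Vector or list of items.
#' @param ratio Training fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return `list(train = ..., validation = ...)` with
#'   `length(train) == round(ratio * length(items))`.
#' @export
#' @examples
#' splitDataset(letters[1:10], 0.8, seed = 1)
splitDataset <- function(items, ratio = 0.8, seed = 1) {
  n <- length(items)
  if (n == 0) stop("empty item list")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  perm <- withSeed(seed, function() sample.int(n))
  nTrain <- round(ratio * n)
  list(train = items[sort(perm[seq_len(nTrain)])],
       validation = items[sort(perm[setdiff(seq_len(n), seq_len(nTrain))])])
}

#' Replay detector backend
#'
#' Wraps a set of annotation records as a pluggable detector backend: calling
#' the returned function with an image id replays the stored boxes as
#' detections with confidence 1.0. This lets the whole pipeline run without
#' a trained object-detection model.
#'
#' @param records Named list of detection data.frames keyed by image id
#'   (e.g. from [readAnnotations()], keyed by their `"image_id"` attribute).
#' @return `function(imageId) -> detections`; unknown ids yield zero
#'   detections.
#' @export
makeReplayBackend <- function(records) {
  force(records)
  function(imageId) {
    det <- records[[imageId]]
    if (is.null(det)) return(emptyDetections())
    det$confidence <- 1.0
    det
  }
}
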