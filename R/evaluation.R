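# Detection evaluation: IoU, per-class average precision at IoU 0.5, mAP50.

#' Intersection over union of two bounding boxes
#'
#' Boxes are 0-based half-open pixel intervals, so areas and intersections
#' are unambiguous: `iou(c(0,0,10,10), c(5,0,15,10))` is `50/150 = 1/3`.
#'
#' @param a,b Numeric boxes `c(x_min, y_min, x_max, y_max)`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  assertBox(a)
  assertBox(b)
  iw <- min(a[3L], b[3L]) - max(a[1L], b[1L])
  ih <- min(a[4L], b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (boxArea(a) + boxArea(b) - inter)
}

# Average precision from per-prediction TP flags (already sorted by
# descending confidence) and the number of ground-truth boxes.
averagePrecision <- function(tp, nTruth, interpolation = "all") {
  if (nTruth == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  cumTp <- cumsum(tp)
  precision <- cumTp / seq_along(tp)
  recall <- cumTp / nTruth
  if (interpolation == "11point") {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      p <- precision[recall >= r]
      if (length(p)) max(p) else 0
    }, numeric(1)))
  } else {
    # all-point interpolation: area under the precision envelope
    precision <- rev(cummax(rev(precision)))
    r <- c(0, recall)
    sum((r[-1L] - r[-length(r)]) * precision)
  }
}

#' Evaluate detections against ground truth (mAP50)
#'
#' Computes per-class average precision at IoU >= 0.5 and their mean (mAP50)
#' over all classes with at least one ground-truth instance. Matching is
#' greedy per class: predictions are visited in order of descending
#' confidence (ties broken by input order) and matched to the unmatched
#' ground-truth box of the same image with the highest IoU; a truth box can
#' be matched at most once, and a prediction whose best IoU is below the
#' threshold - or whose truth box is already taken - counts as a false
#' positive. AP uses all-point interpolation by default (the continuous
#' precision-recall area used by modern detector toolkits); an 11-point mode
#' is available.
#'
#' @param predictions Detection data.frame with columns `image_id`, `class`,
#'   `x_min`, `y_min`, `x_max`, `y_max` and a non-missing `confidence`.
#' @param truth Ground-truth data.frame with the same box columns (no
#'   confidence needed).
#' @param iouThreshold Match threshold, default 0.5.
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return `list(perClass = <named numeric>, map50 = <numeric>)`.
#' @export
#' @examples
#' truth <- data.frame(image_id = "f0", class = "Chair",
#'                     x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' pred <- cbind(truth, confidence = 1)
#' evaluateMap50(pred, truth)$map50   # 1.0
evaluateMap50 <- function(predictions, truth, iouThreshold = 0.5,
                          interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  for (d in list(predictions, truth)) {
    if (!all(c("image_id", "class", "x_min", "y_min", "x_max", "y_max") %in% names(d))) {
      stop("prediction/truth tables need image_id, class and box columns")
    }
  }
  if (nrow(predictions) > 0 &&
      (!"confidence" %in% names(predictions) || anyNA(predictions$confidence))) {
    stop("every prediction must carry a confidence")
  }
  classes <- unique(truth$class)
  if (length(classes) == 0) stop("ground truth is empty")
  perClass <- vapply(classes, function(cl) {
    gt <- truth[truth$class == cl, , drop = FALSE]
    pr <- predictions[predictions$class == cl, , drop = FALSE]
    ord <- order(-pr$confidence)  # stable: ties keep input order
    pr <- pr[ord, , drop = FALSE]
    matched <- logical(nrow(gt))
    tp <- logical(nrow(pr))
    for (i in seq_len(nrow(pr))) {
      cand <- which(gt$image_id == pr$image_id[i] & !matched)
      if (length(cand) == 0) next
      pbox <- as.numeric(pr[i, c("x_min", "y_min", "x_max", "y_max")])
      ious <- vapply(cand, function(j) {
        iou(pbox, as.numeric(gt[j, c("x_min", "y_min", "x_max", "y_max")]))
      }, numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iouThreshold) {
        matched[cand[best]] <- TRUE
        tp[i] <- TRUE
      }
    }
    averagePrecision(tp, nrow(gt), interpolation)
  }, numeric(1))
  names(perClass) <- classes
  list(perClass = perClass, map50 = mean(perClass))
}
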