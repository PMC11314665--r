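# Fusion of per-frame environmental context with per-bout gait statistics,
# and the contextualized gait report.

#' Assign context frames to walking bouts by timestamp
#'
#' A frame belongs to the bout whose interval contains its timestamp, with
#' `tolerance` seconds of slack at either edge; frames outside every bout
#' stay unassigned (`NA`). When edge tolerances of adjacent bouts both catch
#' a frame, the nearer bout wins. Video and IMU clocks are assumed
#' pre-synchronized to a common epoch; apply `clockOffset` (added to frame
#' timestamps) when they are not.
#'
#' @param contexts Time-ordered frame-context data.frame (from
#'   [contextualizeFrames()]) with a `timestamp` column.
#' @param bouts Time-ordered, non-overlapping bout data.frame with `start`
#'   and `end` columns (from [detectBouts()]).
#' @param tolerance Edge slack in seconds (>= 0), default 0.
#' @param clockOffset Constant offset added to frame timestamps, seconds.
#' @return `contexts` with an integer `bout` column (`NA` = unassigned).
#' @export
alignContexts <- function(contexts, bouts, tolerance = 0, clockOffset = 0) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (is.unsorted(contexts$timestamp)) stop("contexts must be time-ordered")
  if (nrow(bouts) > 0 && (is.unsorted(bouts$start) ||
      any(bouts$end[-nrow(bouts)] > bouts$start[-1L]))) {
    stop("bouts must be time-ordered and non-overlapping")
  }
  ts <- contexts$timestamp + clockOffset
  contexts$bout <- vapply(ts, function(t) {
    d <- pmax(bouts$start - t, t - bouts$end, 0)
    hit <- which(d <= tolerance)
    if (length(hit) == 0) NA_integer_ else hit[which.min(d[hit])]
  }, integer(1))
  contexts
}

#' Summarize environmental context per walking bout
#'
#' Aggregates aligned frame contexts (and their per-detection verdicts) into
#' one context summary per bout: the fraction of frames with a fall-risk
#' detection in the walking path, the fraction with gaze on the path,
#' per-class in-path frame counts, and the number of unattended hazard
#' windows - fixed-length attention windows (see [attentionOnHazards()]) in
#' which hazards were present in the path but never gazed.
#'
#' @param contexts Frame contexts with a `bout` column from
#'   [alignContexts()].
#' @param verdicts Per-detection verdict table from [contextualizeFrames()]
#'   (matched to contexts by `frame_index`); optional, `NULL` drops the
#'   per-class counts.
#' @param bouts The bout table the contexts were aligned to.
#' @param taxonomy A [ClassTaxonomy-class].
#' @param window Attention window length in seconds, default 5.
#' @return List with one summary per bout: `bout`, `n_frames`,
#'   `hazard_in_path_fraction`, `gaze_on_path_fraction`,
#'   `in_path_class_counts` (named integer vector),
#'   `unattended_hazard_windows`. Bouts with zero assigned frames carry `NA`
#'   fractions.
#' @export
summarizeBoutContexts <- function(contexts, verdicts, bouts, taxonomy,
                                  window = 5) {
  if (!"bout" %in% names(contexts)) stop("contexts must be aligned first")
  lapply(seq_len(nrow(bouts)), function(b) {
    sel <- contexts[!is.na(contexts$bout) & contexts$bout == b, , drop = FALSE]
    nf <- nrow(sel)
    counts <- NULL
    if (!is.null(verdicts) && nf > 0) {
      vv <- verdicts[verdicts$frame_index %in% sel$frame_index &
                       verdicts$in_path, , drop = FALSE]
      counts <- table(factor(vv$class, levels = classNames(taxonomy)))
      counts <- as.integer(counts)
      names(counts) <- classNames(taxonomy)
      counts <- counts[counts > 0]
    }
    unattended <- 0L
    if (nf > 0 && any(sel$hazard_in_path)) {
      att <- attentionOnHazards(sel, window)
      unattended <- sum(att$n_hazard_frames > 0 & att$attention_fraction == 0,
                        na.rm = TRUE)
    }
    list(bout = b, n_frames = nf,
         hazard_in_path_fraction = if (nf > 0) mean(sel$hazard_in_path) else NA_real_,
         gaze_on_path_fraction = if (nf > 0) mean(sel$gaze_on_path) else NA_real_,
         in_path_class_counts = counts,
         unattended_hazard_windows = unattended)
  })
}

#' Build a contextualized gait report
#'
#' Combines per-bout temporal gait statistics with per-bout environmental
#' context summaries, optionally against normative (e.g. lab-walk) statistics
#' for the same person: when `normative` is given, each bout also reports the
#' statistic-minus-normative deltas. The report deliberately stops at the
#' ingredients - gait, context, attention - and assigns no fall-risk score.
#'
#' @param boutStats List of [GaitStats-class] (or `NA` for bouts without
#'   usable events), one per bout.
#' @param boutSummaries List from [summarizeBoutContexts()], same length.
#' @param bouts The bout table (`start`, `end`).
#' @param normative Optional [GaitStats-class] of normative values.
#' @return A `ContextualizedGaitReport`: a list with elements `bouts` (list
#'   of per-bout entries) and `normative` (or `NULL`).
#' @export
buildReport <- function(boutStats, boutSummaries, bouts, normative = NULL) {
  if (length(boutStats) != nrow(bouts) || length(boutSummaries) != nrow(bouts)) {
    stop("bout mismatch: stats, summaries and bout table must align")
  }
  entries <- lapply(seq_len(nrow(bouts)), function(b) {
    s <- boutStats[[b]]
    gait <- if (is(s, "GaitStats")) as.list(as.data.frame(s)) else NULL
    delta <- NULL
    if (!is.null(gait) && is(normative, "GaitStats")) {
      nv <- as.list(as.data.frame(normative))
      delta <- mapply(function(a, b) a - b, gait, nv, SIMPLIFY = FALSE)
    }
    sm <- boutSummaries[[b]]
    list(bout = b, start = bouts$start[b], end = bouts$end[b],
         gait = gait, delta = delta,
         context = sm[setdiff(names(sm), "bout")])
  })
  structure(list(bouts = entries,
                 normative = if (is(normative, "GaitStats")) {
                   as.list(as.data.frame(normative))
                 } else {
                   NULL
                 }),
            class = "ContextualizedGaitReport")
}

#' @export
print.ContextualizedGaitReport <- function(x, ...) {
  cat("ContextualizedGaitReport:", length(x$bouts), "bout(s)",
      if (!is.null(x$normative)) "(with normative deltas)" else "", "\n")
  invisible(x)
}

#' Serialize a contextualized gait report
#'
#' `writeReportJSON()` / `readReportJSON()` round-trip a report losslessly
#' through JSON; `reportToDataFrame()` flattens it to one row per bout with
#' the 9 temporal-statistics columns, context fractions and (when present)
#' normative deltas, suitable for CSV export.
#'
#' @param report A `ContextualizedGaitReport` from [buildReport()].
#' @param path File path.
#' @return `writeReportJSON()` returns `path` invisibly; `readReportJSON()`
#'   the report; `reportToDataFrame()` a data.frame.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReportJSON
#' @export
readReportJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$bouts <- lapply(x$bouts, function(e) {
    for (f in c("gait", "delta")) {
      if (!is.null(e[[f]])) e[[f]] <- lapply(e[[f]], as.numeric)
    }
    cc <- e$context$in_path_class_counts
    if (!is.null(cc)) {
      e$context$in_path_class_counts <-
        stats::setNames(as.integer(unlist(cc)), names(cc))
    }
    e
  })
  structure(x, class = "ContextualizedGaitReport")
}

#' @rdname writeReportJSON
#' @export
reportToDataFrame <- function(report) {
  rows <- lapply(report$bouts, function(e) {
    base <- data.frame(bout = e$bout, start = e$start, end = e$end)
    statNames <- paste(rep(c("step", "stance", "swing"), each = 3),
                       c("mean", "std", "asy"), sep = "_")
    gait <- if (is.null(e$gait)) {
      stats::setNames(as.list(rep(NA_real_, 9)), statNames)
    } else {
      e$gait
    }
    ctx <- e$context
    num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(unlist(x))
    out <- cbind(base, as.data.frame(gait),
                 data.frame(
                   n_frames = num1(ctx$n_frames),
                   hazard_in_path_fraction = num1(ctx$hazard_in_path_fraction),
                   gaze_on_path_fraction = num1(ctx$gaze_on_path_fraction),
                   unattended_hazard_windows = num1(ctx$unattended_hazard_windows)))
    if (!is.null(e$delta)) {
      d <- as.data.frame(e$delta)
      names(d) <- paste0("delta_", names(d))
      out <- cbind(out, d)
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
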