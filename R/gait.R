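# Lower-back accelerometer gait processing: walking-bout segmentation,
# initial/final contact event detection, temporal gait characteristics.

#' Read and write tri-axial accelerometer CSVs
#'
#' The CSV carries a `time` column (seconds) plus three acceleration columns.
#' Axis-to-anatomy mapping is declared via `axisMap`: a named character
#' vector mapping the anatomical channels `v` (vertical), `ap`
#' (anteroposterior) and `ml` (mediolateral) to column names in the file.
#' Units are declared, not guessed.
#'
#' @param path CSV file.
#' @param axisMap Named character vector, default
#'   `c(v = "v", ap = "ap", ml = "ml")`.
#' @param units `"m/s^2"` (default) or `"g"`.
#' @param signal An [AccelSignal-class] (for writing).
#' @return `readAccelCSV()` returns an [AccelSignal-class];
#'   `writeAccelCSV()` returns `path` invisibly.
#' @export
readAccelCSV <- function(path, axisMap = c(v = "v", ap = "ap", ml = "ml"),
                         units = "m/s^2") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", unname(axisMap))
  if (!all(need %in% names(d))) {
    stop("accelerometer CSV ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  AccelSignal(time = d$time, v = d[[axisMap[["v"]]]],
              ap = d[[axisMap[["ap"]]]], ml = d[[axisMap[["ml"]]]],
              units = units)
}

#' @rdname readAccelCSV
#' @export
writeAccelCSV <- function(signal, path) {
  stopifnot(is(signal, "AccelSignal"))
  utils::write.csv(
    data.frame(time = signal@time, v = signal@acc[, "v"],
               ap = signal@acc[, "ap"], ml = signal@acc[, "ml"]),
    path, row.names = FALSE)
  invisible(path)
}

# Moving standard deviation over a centred window of n samples (NA at edges).
movingSD <- function(x, n) {
  if (n < 2) stop("window too short")
  k <- rep(1 / n, n)
  m1 <- stats::filter(x, k, sides = 2)
  m2 <- stats::filter(x^2, k, sides = 2)
  sqrt(pmax(as.numeric(m2 - m1^2), 0) * n / (n - 1))
}

#' Segment walking bouts from an accelerometer trace
#'
#' Flags samples where the moving standard deviation of the acceleration
#' magnitude over a short window exceeds an activity threshold, merges
#' active runs separated by brief gaps, and discards runs shorter than a
#' minimum duration. This reproduces the role of validated walking/activity
#' segmentation at desk scale; every parameter is configurable.
#'
#' @param signal An [AccelSignal-class] (>= 1 s of data).
#' @param activityThreshold Threshold on the moving STD of acceleration
#'   magnitude, in g; default 0.05.
#' @param window Moving-STD window in seconds; default 0.5.
#' @param mergeGap Gaps between active runs shorter than this (seconds) are
#'   merged; default 0.3.
#' @param minDuration Bouts shorter than this (seconds) are discarded;
#'   default 3.
#' @return data.frame with columns `start`, `end` (seconds), one row per
#'   bout, time-ordered and non-overlapping.
#' @export
detectBouts <- function(signal, activityThreshold = 0.05, window = 0.5,
                        mergeGap = 0.3, minDuration = 3) {
  stopifnot(is(signal, "AccelSignal"))
  if (diff(range(signal@time)) < 1) stop("at least 1 s of data is required")
  mag <- sqrt(rowSums(signal@acc^2))
  if (signal@units == "m/s^2") mag <- mag / STANDARD_GRAVITY
  n <- max(3L, round(window * signal@sampleRate))
  active <- movingSD(mag, n) > activityThreshold
  active[is.na(active)] <- FALSE
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = signal@time[starts[r$values]],
                     end = signal@time[ends[r$values]])
  if (nrow(runs) == 0) return(runs)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] < mergeGap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  out <- merged[merged$end - merged$start >= minDuration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dominant step frequency of a signal segment
#'
#' Periodogram peak within a physiological band (default 1.4-3 Hz, covering
#' usual adult walking cadences).
#'
#' @param x Numeric signal segment.
#' @param sampleRate Hz.
#' @param range Frequency band `c(lo, hi)` in Hz.
#' @return Peak frequency in Hz (band midpoint when the band holds no bins).
#' @export
estimateStepFrequency <- function(x, sampleRate, range = c(1.4, 3)) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * sampleRate / n
  sel <- which(f >= range[1L] & f <= range[2L])
  if (length(sel) == 0) return(mean(range))
  f[sel[which.max(P[sel])]]
}

# Convolve x with the derivative-of-Gaussian (DoG) kernel of scale sigma
# seconds: returns d/dt of the Gaussian-smoothed signal (NA at the edges).
dogFilter <- function(x, sampleRate, sigma) {
  r <- ceiling(4 * sigma * sampleRate)
  # stats::filter cross-correlates (f[1] applied at the future side), so the
  # antisymmetric DoG kernel must be supplied mirrored.
  tau <- (r:(-r)) / sampleRate
  kern <- tau / sigma^2 * exp(-tau^2 / (2 * sigma^2)) / sampleRate
  as.numeric(stats::filter(x, kern, sides = 2))
}

# Local extrema indices with prominence fraction and minimum separation
# (in samples); deepest/highest candidates win ties within a separation.
pickExtrema <- function(s, minima = TRUE, fraction = 0.4, minSep = 1L) {
  if (minima) s <- -s
  ok <- !is.na(s)
  if (sum(ok) < 3) return(integer(0))
  i <- which(ok)[-c(1, sum(ok))]
  cand <- i[s[i] > s[i - 1L] & s[i] >= s[i + 1L]]
  if (length(cand) == 0) return(integer(0))
  mu <- mean(s, na.rm = TRUE)
  thr <- mu + fraction * (max(s, na.rm = TRUE) - mu)
  cand <- cand[s[cand] > thr]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(-s[cand])]
  keep <- integer(0)
  for (c0 in cand) {
    if (all(abs(keep - c0) >= minSep)) keep <- c(keep, c0)
  }
  sort(keep)
}

# Sub-sample extremum refinement by parabolic interpolation.
refineExtremum <- function(s, idx, time) {
  dt <- time[2L] - time[1L]
  vapply(idx, function(i) {
    if (i <= 1 || i >= length(s) || anyNA(s[(i - 1):(i + 1)])) return(time[i])
    den <- s[i - 1L] - 2 * s[i] + s[i + 1L]
    delta <- if (abs(den) < 1e-12) 0 else 0.5 * (s[i - 1L] - s[i + 1L]) / den
    time[i] + max(min(delta, 0.5), -0.5) * dt
  }, numeric(1))
}

#' Detect initial- and final-contact events within a walking bout
#'
#' Follows the established approach for a lower-back (L5) wearable: the
#' vertical acceleration is mean-detrended, integrated, and differentiated
#' with a derivative-of-Gaussian (continuous wavelet) filter. Initial
#' contacts (IC, heel strike) are the local minima of this once-
#' differentiated smoothed signal; final contacts (FC, toe off) are the
#' local maxima after a second wavelet differentiation. The smoothing scale
#' defaults to a fraction of the step period estimated from the spectral
#' peak in `stepFreqRange`. Alternation is then enforced: each surviving FC
#' lies strictly between two consecutive ICs, keeping the most extreme
#' response when several compete for the same gap.
#'
#' A constant (motionless) segment yields zero events.
#'
#' @param signal An [AccelSignal-class].
#' @param bout One bout as `c(start, end)` seconds or a one-row data.frame
#'   from [detectBouts()].
#' @param stepFreqRange Band for the step-frequency estimate (Hz).
#' @param smoothSigma Gaussian smoothing scale in seconds; default one
#'   sixteenth of the estimated step period.
#' @param peakFraction Prominence fraction for extremum candidates,
#'   default 0.4.
#' @return A [GaitEvents-class].
#' @export
detectGaitEvents <- function(signal, bout, stepFreqRange = c(1.4, 3),
                             smoothSigma = NULL, peakFraction = 0.4) {
  stopifnot(is(signal, "AccelSignal"))
  if (is.data.frame(bout)) bout <- c(bout$start[1L], bout$end[1L])
  if (bout[1L] < signal@time[1L] - 1e-9 ||
      bout[2L] > signal@time[length(signal@time)] + 1e-9) {
    stop("bout lies outside the signal span")
  }
  sel <- signal@time >= bout[1L] & signal@time <= bout[2L]
  tt <- signal@time[sel]
  v <- signal@acc[sel, "v"]
  v <- v - mean(v)                     # gravity/orientation detrend
  if (stats::sd(v) < 1e-9) return(GaitEvents())
  fs <- signal@sampleRate
  fstep <- estimateStepFrequency(v, fs, stepFreqRange)
  if ((bout[2L] - bout[1L]) * fstep < 3) {
    stop("bout shorter than 3 expected steps")
  }
  if (is.null(smoothSigma)) smoothSigma <- 1 / (16 * fstep)
  vi <- cumsum(v) / fs
  fit <- stats::lm.fit(cbind(1, tt), vi)   # drift removal after integration
  vi <- vi - fit$fitted.values
  s1 <- dogFilter(vi, fs, smoothSigma)     # ~ Gaussian-smoothed acceleration
  s2 <- dogFilter(s1, fs, smoothSigma)     # ~ smoothed jerk
  minSep <- max(1L, round(0.45 / fstep * fs))
  icIdx <- pickExtrema(s1, minima = TRUE, fraction = peakFraction, minSep = minSep)
  fcIdx <- pickExtrema(s2, minima = FALSE, fraction = peakFraction, minSep = minSep)
  ic <- refineExtremum(s1, icIdx, tt)
  if (length(ic) < 2 || length(fcIdx) == 0) {
    return(GaitEvents(ic = ic, fc = numeric(0)))
  }
  # alternation: at most one FC per inter-IC gap, keeping the strongest
  fcT <- refineExtremum(s2, fcIdx, tt)
  gap <- findInterval(fcT, ic)
  inside <- gap >= 1 & gap < length(ic) & !fcT %in% ic
  fcIdx <- fcIdx[inside]
  fcT <- fcT[inside]
  gap <- gap[inside]
  keep <- unlist(lapply(split(seq_along(fcT), gap), function(ii) {
    ii[which.max(s2[fcIdx[ii]])]
  }), use.names = FALSE)
  GaitEvents(ic = ic, fc = fcT[sort(keep)])
}

# |mean over even positions - mean over odd positions|, respecting the
# original series index parity (NA entries are skipped).
alternatingAsymmetry <- function(x) {
  k <- seq_along(x)
  even <- x[k %% 2 == 0]
  odd <- x[k %% 2 == 1]
  if (all(is.na(even)) || all(is.na(odd))) return(NA_real_)
  abs(mean(even, na.rm = TRUE) - mean(odd, na.rm = TRUE))
}

seriesStats <- function(x) {
  ok <- !is.na(x)
  c(mean = mean(x[ok]),
    std = if (sum(ok) >= 2) stats::sd(x[ok]) else 0,
    asy = alternatingAsymmetry(x))
}

#' Temporal gait characteristics from IC/FC events
#'
#' With initial contacts `t_1 < t_2 < ...` and final contacts interleaved so
#' that the FC of the stride starting at `t_k` falls between `t_(k+1)` and
#' `t_(k+2)`:
#' \itemize{
#'   \item step time `step_k = t_(k+1) - t_k`;
#'   \item stride time `stride_k = t_(k+2) - t_k`;
#'   \item stance time `stance_k = FC_(k+1) - t_k` (the FC following
#'     `IC_(k+1)`);
#'   \item swing time `swing_k = stride_k - stance_k` (so
#'     `stance_k + swing_k = stride_k` holds exactly by construction).
#' }
#' For each series the mean, standard deviation and asymmetry are reported.
#' Asymmetry is the absolute difference between the means over even- and
#' odd-indexed elements - alternating elements are a proxy for left/right
#' sides, which a single lower-back sensor cannot label.
#'
#' @param events A [GaitEvents-class] with at least 4 ICs and interleaved
#'   FCs.
#' @return A [GaitStats-class].
#' @export
#' @examples
#' ev <- GaitEvents(ic = c(0, 0.5, 1, 1.5, 2), fc = c(0.7, 1.2, 1.7))
#' statsMatrix(computeTemporalStats(ev))
computeTemporalStats <- function(events) {
  stopifnot(is(events, "GaitEvents"))
  ic <- events@ic
  fc <- events@fc
  n <- length(ic)
  if (n < 4) stop("too few events: at least 4 initial contacts are required")
  if (length(fc) == 0) stop("too few events: no final contacts")
  gap <- findInterval(fc, ic)
  if (any(gap < 1) || any(gap >= n) || anyDuplicated(gap)) {
    stop("alternation violated: each FC must lie in its own inter-IC gap")
  }
  fcByGap <- rep(NA_real_, n - 1)
  fcByGap[gap] <- fc
  step <- diff(ic)
  stride <- ic[-(1:2)] - ic[seq_len(n - 2)]
  stance <- fcByGap[-1L][seq_len(n - 2)] - ic[seq_len(n - 2)]
  swing <- stride - stance
  values <- rbind(step = seriesStats(step), stance = seriesStats(stance),
                  swing = seriesStats(swing))
  colnames(values) <- c("mean", "std", "asy")
  new("GaitStats", values = values,
      n = c(step = length(step), stance = sum(!is.na(stance)),
            swing = sum(!is.na(swing))))
}

#' Per-bout temporal gait report for a whole recording
#'
#' Convenience wrapper: segments walking bouts, detects gait events in each
#' and computes temporal statistics, returning one row per bout (bouts with
#' too few detected events are kept with `NA` statistics).
#'
#' @param signal An [AccelSignal-class].
#' @param bouts Optional precomputed bout table; segmented with defaults
#'   when omitted.
#' @param ... Passed to [detectGaitEvents()].
#' @return data.frame with `bout`, `start`, `end`, `n_ic` and the 9
#'   statistics columns `step_mean` ... `swing_asy`.
#' @export
gaitReport <- function(signal, bouts = NULL, ...) {
  if (is.null(bouts)) bouts <- detectBouts(signal)
  rows <- lapply(seq_len(nrow(bouts)), function(i) {
    base <- data.frame(bout = i, start = bouts$start[i], end = bouts$end[i])
    ev <- tryCatch(detectGaitEvents(signal, c(bouts$start[i], bouts$end[i]), ...),
                   error = function(e) GaitEvents())
    stats <- tryCatch(as.data.frame(computeTemporalStats(ev)),
                      error = function(e) {
                        out <- as.data.frame(as.list(rep(NA_real_, 9)))
                        names(out) <- paste(rep(c("step", "stance", "swing"), each = 3),
                                            c("mean", "std", "asy"), sep = "_")
                        out
                      })
    cbind(base, n_ic = length(icTimes(ev)), stats)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
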