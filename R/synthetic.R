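# Synthetic scene sequences and gait signals with full ground truth. The
# truths are computed independently of the modules under test: scene overlap
# truth comes from continuous per-pixel geometry (not the mask engine), gait
# truth from the planted event timestamps (not the detector).

# Distance from a point to an axis-aligned box (0 inside).
pointBoxDistance <- function(px, py, box) {
  dx <- max(0, box[1L] - px, px - box[3L])
  dy <- max(0, box[2L] - py, py - box[4L])
  sqrt(dx^2 + dy^2)
}

expandBox <- function(box, margin) {
  box + c(-margin, -margin, margin, margin)
}

# Seeded value-noise background texture (coarse random grid, bilinear
# upsampling), so blurring measurably changes pixels everywhere.
valueNoise <- function(height, width, grid = 9, lo = 40, hi = 215) {
  g <- matrix(stats::runif(grid * grid), grid, grid)
  gx <- seq(1, grid, length.out = width)
  gy <- seq(1, grid, length.out = height)
  x0 <- pmin(floor(gx), grid - 1L)
  y0 <- pmin(floor(gy), grid - 1L)
  fx <- gx - x0
  fy <- gy - y0
  a <- g[cbind(rep(y0, width), rep(x0, each = height))]
  b <- g[cbind(rep(y0, width), rep(x0 + 1L, each = height))]
  cc <- g[cbind(rep(y0 + 1L, width), rep(x0, each = height))]
  d <- g[cbind(rep(y0 + 1L, width), rep(x0 + 1L, each = height))]
  fxm <- rep(fx, each = height)
  fym <- rep(fy, width)
  v <- a * (1 - fxm) * (1 - fym) + b * fxm * (1 - fym) +
    cc * (1 - fxm) * fym + d * fxm * fym
  matrix(round(lo + v * (hi - lo)), nrow = height)
}

classColour <- function(classIdx) {
  c((37 * classIdx + 23) %% 200 + 28,
    (91 * classIdx + 67) %% 200 + 28,
    (151 * classIdx + 131) %% 200 + 28)
}

#' Generate a synthetic egocentric scene sequence with ground truth
#'
#' Produces frames with class-labelled rectangles on a textured background, a
#' smooth random-walk gaze trajectory, and per-detection overlap ground truth
#' computed from continuous geometry (independent of the mask-based overlap
#' engine). Per frame, with probability `hazardInPathProb` a fall-risk-role
#' box is planted solidly overlapping the walking path; otherwise any hazard
#' box is placed well clear of the path, so the frame-level hazard truth is a
#' Bernoulli draw with known rate. Context and privacy boxes are placed
#' uniformly at random.
#'
#' @param nFrames Number of frames.
#' @param frameWidth,frameHeight Frame size in pixels.
#' @param fps Frames per second (timestamps run from `startTime`).
#' @param startTime Timestamp of the first frame, seconds.
#' @param meanBoxes Mean number of non-hazard boxes per frame (Poisson).
#' @param boxSizeRange Box side lengths as fractions of frame size.
#' @param hazardInPathProb Probability a frame carries an in-path hazard.
#' @param hazardOffPathProb Probability a frame without an in-path hazard
#'   still shows a hazard, placed clear of the path.
#' @param gazeRadius Gaze circle radius in pixels (used for the gaze truth).
#' @param gazeInvalidProb Probability a frame's gaze sample is dropped.
#' @param pathArgs Named list of [buildWalkingPath()] arguments.
#' @param taxonomy A [ClassTaxonomy-class].
#' @param renderImages Render 8-bit frame images (needed for privacy tests).
#' @param seed Integer seed; the generator is deterministic under a fixed
#'   seed.
#' @return `list(frames = <list of FrameRecord>, images = <list of arrays> or
#'   NULL, truth = list(verdicts, frames), path = <WalkingPath>)`. The truth
#'   verdict table has `frame_index`, `class`, box columns, `true_in_path`
#'   and `true_gazed`; the truth frame table has `frame_index`,
#'   `hazard_in_path` and `hazard_gazed`.
#' @export
#' @examples
#' scene <- generateSceneSequence(nFrames = 5, renderImages = FALSE, seed = 7)
#' scene$truth$frames
generateSceneSequence <- function(nFrames = 100, frameWidth = 640,
                                  frameHeight = 480, fps = 2, startTime = 0,
                                  meanBoxes = 2, boxSizeRange = c(0.08, 0.3),
                                  hazardInPathProb = 0.3,
                                  hazardOffPathProb = 0.5,
                                  gazeRadius = 30, gazeInvalidProb = 0,
                                  pathArgs = list(), taxonomy = loadTaxonomy(),
                                  renderImages = TRUE, seed = NULL) {
  if (any(boxSizeRange <= 0) || any(boxSizeRange > 1)) {
    stop("box sizes are fractions of the frame: a box may not exceed the frame")
  }
  if (hazardInPathProb < 0 || hazardInPathProb > 1) {
    stop("hazardInPathProb must lie in [0, 1]")
  }
  path <- do.call(buildWalkingPath, c(list(frameWidth, frameHeight), pathArgs))
  hazardNames <- hazardClasses(taxonomy)
  otherNames <- setdiff(classNames(taxonomy), hazardNames)
  allNames <- classNames(taxonomy)
  cellW <- frameWidth / 200
  cellH <- frameHeight / 200
  topY <- pathVertices(path)[4L, 2L]

  randomBox <- function() {
    w <- max(20, round(stats::runif(1, boxSizeRange[1L], boxSizeRange[2L]) * frameWidth))
    h <- max(20, round(stats::runif(1, boxSizeRange[1L], boxSizeRange[2L]) * frameHeight))
    x0 <- round(stats::runif(1, 0, frameWidth - w))
    y0 <- round(stats::runif(1, 0, frameHeight - h))
    c(x0, y0, x0 + w, y0 + h)
  }

  withSeed(seed, function() {
    gazeX <- frameWidth / 2
    gazeY <- frameHeight * 0.75
    frames <- vector("list", nFrames)
    images <- if (renderImages) vector("list", nFrames) else NULL
    truthRows <- vector("list", nFrames)
    frameTruth <- vector("list", nFrames)

    for (i in seq_len(nFrames)) {
      cls <- character(0)
      boxes <- matrix(numeric(0), ncol = 4)
      addBox <- function(name, box) {
        cls <<- c(cls, name)
        boxes <<- rbind(boxes, box)
      }
      for (b in seq_len(stats::rpois(1, meanBoxes))) {
        addBox(sample(otherNames, 1L), randomBox())
      }
      # hazard: planted solidly inside the path, or well clear of it
      if (stats::runif(1) < hazardInPathProb) {
        margin <- 4 * cellW + 0.02 * frameWidth
        h <- max(round(6 * cellH), round(0.12 * frameHeight))
        yMax <- round(stats::runif(1, topY + 0.5 * (frameHeight - topY), frameHeight))
        xr <- pathXRange(path, yMax)
        cx <- stats::runif(1, xr[1L] + margin, xr[2L] - margin)
        w <- max(round(6 * cellW), round(0.1 * frameWidth))
        box <- c(max(0, round(cx - w / 2)), max(0, yMax - h),
                 min(frameWidth, round(cx + w / 2)), yMax)
        addBox(sample(hazardNames, 1L), box)
      } else if (stats::runif(1) < hazardOffPathProb) {
        clearance <- 2.5 * max(cellW, cellH) + 2
        for (try in 1:50) {
          box <- randomBox()
          if (!boxIntersectsPath(expandBox(box, clearance), path)) {
            addBox(sample(hazardNames, 1L), box)
            break
          }
        }
      }
      # smooth random-walk gaze, pulled gently towards the lower frame centre
      gazeX <- gazeX + 0.1 * (frameWidth / 2 - gazeX) +
        stats::rnorm(1, 0, 0.03 * frameWidth)
      gazeY <- gazeY + 0.1 * (frameHeight * 0.75 - gazeY) +
        stats::rnorm(1, 0, 0.03 * frameHeight)
      gazeX <- min(max(gazeX, 0), frameWidth - 1)
      gazeY <- min(max(gazeY, 0), frameHeight - 1)
      gazeValid <- stats::runif(1) >= gazeInvalidProb

      n <- length(cls)
      det <- if (n == 0) emptyDetections() else data.frame(
        class = cls, x_min = boxes[, 1L], y_min = boxes[, 2L],
        x_max = boxes[, 3L], y_max = boxes[, 4L],
        confidence = round(stats::runif(n, 0.5, 1), 3),
        stringsAsFactors = FALSE)
      frames[[i]] <- FrameRecord(i - 1L, startTime + (i - 1) / fps,
                                 frameWidth, frameHeight, det,
                                 gazeX = if (gazeValid) gazeX else NA_real_,
                                 gazeY = if (gazeValid) gazeY else NA_real_,
                                 gazeValid = gazeValid)

      # ground truth from continuous geometry, never from the mask engine
      if (n > 0) {
        inPath <- vapply(seq_len(n), function(k) {
          boxIntersectsPath(boxes[k, ], path)
        }, logical(1))
        gazed <- gazeValid & vapply(seq_len(n), function(k) {
          pointBoxDistance(gazeX, gazeY, boxes[k, ]) <= gazeRadius
        }, logical(1))
        truthRows[[i]] <- cbind(
          data.frame(frame_index = i - 1L, class = cls, stringsAsFactors = FALSE),
          data.frame(x_min = boxes[, 1L], y_min = boxes[, 2L],
                     x_max = boxes[, 3L], y_max = boxes[, 4L]),
          data.frame(true_in_path = inPath, true_gazed = gazed))
        hz <- isHazardClass(taxonomy, cls)
        frameTruth[[i]] <- data.frame(frame_index = i - 1L,
                                      hazard_in_path = any(hz & inPath),
                                      hazard_gazed = any(hz & inPath & gazed))
      } else {
        frameTruth[[i]] <- data.frame(frame_index = i - 1L,
                                      hazard_in_path = FALSE,
                                      hazard_gazed = FALSE)
      }

      if (renderImages) {
        img <- array(0L, c(frameHeight, frameWidth, 3L))
        bg <- valueNoise(frameHeight, frameWidth)
        shade <- c(1, 0.95, 0.88)
        for (ch in 1:3) img[, , ch] <- as.integer(round(bg * shade[ch]))
        for (k in seq_len(n)) {
          rows <- (boxes[k, 2L] + 1):boxes[k, 4L]
          colsIdx <- (boxes[k, 1L] + 1):boxes[k, 3L]
          colr <- classColour(match(cls[k], allNames))
          for (ch in 1:3) img[rows, colsIdx, ch] <- colr[ch]
        }
        images[[i]] <- img
      }
    }

    list(frames = frames, images = images,
         truth = list(
           verdicts = if (length(tr <- truthRows[!vapply(truthRows, is.null, logical(1))])) {
             do.call(rbind, c(tr, list(make.row.names = FALSE)))
           } else {
             data.frame()
           },
           frames = do.call(rbind, c(frameTruth, list(make.row.names = FALSE)))),
         path = path)
  })
}

#' Generate a synthetic lower-back gait signal with ground truth
#'
#' Builds a tri-axial accelerometer trace of a single walking bout flanked by
#' rest: the vertical channel is a smooth locomotor oscillation whose trough
#' coincides with each initial contact, plus a sharp negative Gaussian pulse
#' at every true IC and a positive pulse at every true FC, plus white noise.
#' Step times alternate `stepMean + stepOffset/2` / `stepMean - stepOffset/2`
#' (even/odd steps) with Gaussian jitter `stepSD`, so the true step asymmetry
#' is `|stepOffset|` by construction. Each FC is planted at
#' `IC_k + stanceFraction * stride_k`, so the true stance, swing and stride
#' series satisfy `stance + swing = stride` exactly.
#'
#' @param stepMean Mean step time in seconds (> 0), default 0.55.
#' @param stepSD Step-time jitter STD in seconds, default 0.01; must not
#'   exceed `stepMean / 2`.
#' @param stepOffset Even/odd step-time offset in seconds (true asymmetry).
#' @param stanceFraction Stance fraction of stride time, default 0.62.
#' @param duration Walking duration in seconds (>= 10 steps).
#' @param sampleRate Sampling rate in Hz, default 100.
#' @param noiseSD White-noise STD in m/s^2, default 0.1.
#' @param restDuration Quiet rest before and after the bout, seconds.
#' @param oscAmplitude,icAmplitude,fcAmplitude Component amplitudes in m/s^2.
#' @param pulseWidth Gaussian pulse STD in seconds (default 0.021, i.e. about
#'   50 ms full width at half maximum).
#' @param units Output units, `"m/s^2"` (default) or `"g"`.
#' @param seed Integer seed.
#' @return `list(signal = <AccelSignal>, truth = list(ic, fc, step, stride,
#'   stance, swing, stepAsy, bout))`; `stepAsy` is the configured
#'   `|stepOffset|`, `bout` the true walking interval `c(start, end)`.
#' @export
#' @examples
#' g <- generateGaitSignal(duration = 20, seed = 1)
#' head(g$truth$ic)
generateGaitSignal <- function(stepMean = 0.55, stepSD = 0.01, stepOffset = 0,
                               stanceFraction = 0.62, duration = 60,
                               sampleRate = 100, noiseSD = 0.1,
                               restDuration = 10, oscAmplitude = 0.5,
                               icAmplitude = 4, fcAmplitude = 3,
                               pulseWidth = 0.021, units = "m/s^2",
                               seed = NULL) {
  if (stepMean <= 0) stop("stepMean must be positive")
  if (stepSD > stepMean / 2) stop("degenerate config: stepSD exceeds stepMean / 2")
  if (stanceFraction <= 0.5 || stanceFraction >= 1) {
    stop("stanceFraction must lie in (0.5, 1)")
  }
  if (duration < 10 * stepMean) stop("duration must cover at least 10 steps")
  withSeed(seed, function() {
    # plant IC times with alternating even/odd offsets
    ic <- restDuration + 0.6
    repeat {
      k <- length(ic)
      off <- if (k %% 2 == 1) stepOffset / 2 else -stepOffset / 2
      stp <- max(0.25 * stepMean, stepMean + off + stats::rnorm(1, 0, stepSD))
      nxt <- ic[k] + stp
      if (nxt > restDuration + duration - 0.6) break
      ic <- c(ic, nxt)
    }
    n <- length(ic)
    step <- diff(ic)
    stride <- ic[-(1:2)] - ic[seq_len(n - 2)]
    stance <- stanceFraction * stride
    swing <- stride - stance
    fc <- c(ic[1L] + (2 * stanceFraction - 1) * stepMean,  # stride begun pre-bout
            ic[seq_len(n - 2)] + stance)

    total <- 2 * restDuration + duration
    tt <- seq(0, total, by = 1 / sampleRate)
    # locomotor oscillation: trough exactly at each IC
    phase <- stats::approx(ic, seq_len(n) - 1, xout = tt, rule = 2)$y
    env <- pmin(1, pmax(0, (tt - (ic[1L] - 0.5)) / 0.3)) *
      pmin(1, pmax(0, ((ic[n] + 0.5) - tt) / 0.3))
    v <- -oscAmplitude * cos(2 * pi * phase) * env
    addPulses <- function(x, times, amp) {
      for (t0 in times) {
        i0 <- max(1L, floor((t0 - 6 * pulseWidth) * sampleRate))
        i1 <- min(length(tt), ceiling((t0 + 6 * pulseWidth) * sampleRate) + 1L)
        idx <- i0:i1
        x[idx] <- x[idx] + amp * exp(-(tt[idx] - t0)^2 / (2 * pulseWidth^2))
      }
      x
    }
    v <- addPulses(v, ic, -icAmplitude)
    v <- addPulses(v, fc, fcAmplitude)
    v <- v + stats::rnorm(length(tt), 0, noiseSD)
    ap <- 0.3 * oscAmplitude * sin(pi * phase) * env +
      stats::rnorm(length(tt), 0, noiseSD)
    ml <- 0.3 * oscAmplitude * cos(pi * phase) * env +
      stats::rnorm(length(tt), 0, noiseSD)
    scale <- if (units == "g") 1 / STANDARD_GRAVITY else 1
    signal <- AccelSignal(time = tt, v = v * scale, ap = ap * scale,
                          ml = ml * scale, sampleRate = sampleRate,
                          units = units)
    list(signal = signal,
         truth = list(ic = ic, fc = fc, step = step, stride = stride,
                      stance = stance, swing = swing,
                      stepAsy = abs(stepOffset),
                      bout = c(ic[1L] - 0.5, ic[n] + 0.5)))
  })
}
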