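test_that("bout segmentation ignores rest and recovers a flanked walk", {
  # pure still signal: gravity offset plus tiny noise -> no bouts
  set.seed(20)
  fs <- 100
  still <- AccelSignal(v = 9.81 + rnorm(30 * fs, 0, 0.005 * 9.80665),
                       ap = rnorm(30 * fs, 0, 0.005 * 9.80665),
                       ml = rnorm(30 * fs, 0, 0.005 * 9.80665),
                       sampleRate = fs)
  expect_equal(nrow(detectBouts(still)), 0L)

  # 60 s synthetic walk flanked by 10 s rest -> one bout within +/- 0.5 s
  g <- generateGaitSignal(duration = 60, restDuration = 10, seed = 21)
  b <- detectBouts(g$signal)
  expect_equal(nrow(b), 1L)
  expect_lt(abs(b$start[1] - g$truth$bout[1]), 0.5)
  expect_lt(abs(b$end[1] - g$truth$bout[2]), 0.5)
})

test_that("brief gaps merge into one bout; short runs are dropped", {
  fs <- 100
  set.seed(22)
  burst <- function(dur) 3 * sin(2 * pi * 2 * seq(0, dur, by = 1 / fs))
  quiet <- function(dur) rep(0, round(dur * fs))
  v <- c(quiet(5), burst(4), quiet(0.2), burst(4), quiet(5))
  v <- v + rnorm(length(v), 0, 0.02)
  sig <- AccelSignal(v = v, sampleRate = fs)
  b <- detectBouts(sig, mergeGap = 0.3)
  expect_equal(nrow(b), 1L)              # 0.2 s gap < mergeGap merges
  # a 2 s run alone is below minDuration = 3 s
  v2 <- c(quiet(5), burst(2), quiet(5))
  v2 <- v2 + rnorm(length(v2), 0, 0.02)
  expect_equal(nrow(detectBouts(AccelSignal(v = v2, sampleRate = fs))), 0L)
})

test_that("event detection returns nothing for constant input and errors on short bouts", {
  fs <- 100
  flat <- AccelSignal(v = rep(9.81, 10 * fs), sampleRate = fs)
  ev <- detectGaitEvents(flat, c(2, 8))
  expect_length(icTimes(ev), 0L)
  g <- generateGaitSignal(duration = 20, seed = 23)
  expect_error(detectGaitEvents(g$signal, c(11, 12)), "3 expected steps")
  expect_error(detectGaitEvents(g$signal, c(-5, 10)), "outside the signal")
})

test_that("planted gait events are recovered precisely", {
  g <- generateGaitSignal(duration = 60, stepMean = 0.55, stepSD = 0.01,
                          stepOffset = 0.05, seed = 24)
  b <- detectBouts(g$signal)
  ev <- detectGaitEvents(g$signal, c(b$start[1], b$end[1]))
  ic <- icTimes(ev)
  # step counts agree within one
  expect_lte(abs(length(ic) - length(g$truth$ic)), 1)
  # >= 95% of true ICs matched within 30 ms
  d <- vapply(g$truth$ic, function(t) min(abs(ic - t)), numeric(1))
  expect_gte(mean(d <= 0.03), 0.95)
  # FCs land within the alternation structure (one per inter-IC gap)
  fc <- fcTimes(ev)
  gap <- findInterval(fc, ic)
  expect_true(all(gap >= 1 & gap < length(ic)))
  expect_false(anyDuplicated(gap) > 0)
})

test_that("temporal statistics match hand-computed values", {
  ev <- GaitEvents(ic = c(0, 0.5, 1, 1.5, 2), fc = c(0.7, 1.2, 1.7))
  m <- statsMatrix(computeTemporalStats(ev))
  expect_equal(unname(m["step", ]), c(0.5, 0, 0))
  expect_equal(unname(m["stance", ]), c(0.7, 0, 0))
  expect_equal(unname(m["swing", ]), c(0.3, 0, 0))

  # alternating 0.5 / 0.6 s steps over 20 steps
  ic <- cumsum(c(0, rep(c(0.5, 0.6), 10)))
  fc <- ic[seq_len(19)] + 0.62 * (ic[3:21] - ic[seq_len(19)])
  m2 <- statsMatrix(computeTemporalStats(GaitEvents(ic = ic, fc = fc)))
  expect_equal(unname(m2["step", "mean"]), 0.55, tolerance = 1e-3)
  expect_equal(unname(m2["step", "asy"]), 0.1, tolerance = 1e-9)
})

test_that("temporal statistics enforce their preconditions", {
  expect_error(computeTemporalStats(GaitEvents(ic = c(0, 0.5, 1))),
               "at least 4")
  expect_error(computeTemporalStats(GaitEvents(ic = c(0, 0.5, 1, 1.5))),
               "no final contacts")
  expect_error(GaitEvents(ic = c(0, 0.5, 1, 1.5), fc = c(0.6, 0.7)),
               "alternation")
})

test_that("stance + swing equals stride exactly, and stats are shift-invariant", {
  g <- generateGaitSignal(duration = 40, stepOffset = 0.03, seed = 25)
  b <- detectBouts(g$signal)
  ev <- detectGaitEvents(g$signal, c(b$start[1], b$end[1]))
  ic <- icTimes(ev); fc <- fcTimes(ev)
  n <- length(ic)
  gap <- findInterval(fc, ic)
  fcByGap <- rep(NA_real_, n - 1); fcByGap[gap] <- fc
  stride <- ic[-(1:2)] - ic[seq_len(n - 2)]
  stance <- fcByGap[-1][seq_len(n - 2)] - ic[seq_len(n - 2)]
  swing <- stride - stance
  m <- statsMatrix(computeTemporalStats(ev))
  # identity holds exactly by construction, so the means add up exactly
  ok <- !is.na(stance)
  expect_identical((stance + swing)[ok], stride[ok])
  expect_equal(m["stance", "mean"] + m["swing", "mean"],
               mean(stride[!is.na(stance)]))
  # symmetric gait: mean step ~ mean stride / 2
  expect_lt(abs(m["step", "mean"] - mean(stride) / 2), 0.01)
  # time-shift invariance
  shifted <- GaitEvents(ic = ic + 1234.5, fc = fc + 1234.5)
  expect_equal(statsMatrix(computeTemporalStats(shifted)), m, tolerance = 1e-9)
})

test_that("configured step timing is recovered across cadences", {
  for (mu in c(0.45, 0.7)) {
    g <- generateGaitSignal(duration = 60, stepMean = mu, stepSD = 0.02,
                            seed = 26 + round(mu * 100))
    b <- detectBouts(g$signal)
    ev <- detectGaitEvents(g$signal, c(b$start[1], b$end[1]))
    m <- statsMatrix(computeTemporalStats(ev))
    expect_lt(abs(m["step", "mean"] - mu), 0.01)
  }
})

test_that("accelerometer CSVs round-trip through read and write", {
  g <- generateGaitSignal(duration = 10, seed = 27)
  f <- tempfile(fileext = ".csv")
  writeAccelCSV(g$signal, f)
  back <- readAccelCSV(f)
  expect_equal(back@acc, g$signal@acc, tolerance = 1e-12)
  expect_equal(back@sampleRate, g$signal@sampleRate, tolerance = 1e-6)
  expect_error(readAccelCSV(f, axisMap = c(v = "nope", ap = "ap", ml = "ml")),
               "columns")
})
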