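test_that("measurement windows match the analysis definitions", {
  w <- measurementWindow("PERISACC")
  expect_equal(w$intervalMs, c(0, 50))
  expect_equal(w$alignEvent, "saccade_on")
  expect_equal(measurementWindow("GO")$intervalMs, c(-50, 25))
  expect_equal(measurementWindow("STIMPEAK")$mode, "most_negative")
  expect_equal(measurementWindow("BASELINE")$intervalMs, c(-300, -200))
})

test_that("window measures reduce series by mean or most-negative value", {
  expect_equal(windowMeasure(1:5, list(intervalMs = c(0, 5), mode = "mean"),
                             timeAxisMs = 0:4), 3)
  expect_equal(windowMeasure(rep(-2, 100),
                             list(intervalMs = c(10, 60),
                                  mode = "most_negative"),
                             timeAxisMs = 0:99), -2)
  # peri-saccadic Gaussian (peak -1 at 25 ms, SD 20): window mean over [0,50)
  lags <- -200:199
  kern <- -exp(-(lags - 25)^2 / (2 * 20^2))
  got <- windowMeasure(kern, measurementWindow("PERISACC"), timeAxisMs = lags)
  oracle <- mean(-exp(-((0:49) - 25)^2 / (2 * 20^2)))   # direct sum
  expect_equal(got, oracle)
  expect_equal(got, -0.79, tolerance = 0.01)
  expect_error(windowMeasure(1:5, measurementWindow("PERISACC"),
                             timeAxisMs = 100:104), "outside")
})

test_that("window means are linear in the series", {
  set.seed(9)
  a <- rnorm(400); b <- rnorm(400)
  w <- measurementWindow("PERISACC"); ax <- -200:199
  expect_equal(windowMeasure(3 * a - 2 * b, w, ax),
               3 * windowMeasure(a, w, ax) - 2 * windowMeasure(b, w, ax))
})

test_that("baseline shift zeroes the baseline window and is idempotent", {
  ax <- -400:199
  expect_equal(baselineShift(rep(7, 600), timeAxisMs = ax), rep(0, 600))
  s <- rep(2, 600)
  s[ax >= 20 & ax < 30] <- -3
  shifted <- baselineShift(s, timeAxisMs = ax)
  expect_equal(min(shifted), -5)
  sel <- ax >= -300 & ax < -200
  set.seed(1)
  r <- rnorm(600)
  once <- baselineShift(r, timeAxisMs = ax)
  expect_equal(mean(once[sel]), 0)
  expect_equal(baselineShift(once, timeAxisMs = ax), once)
  expect_error(baselineShift(1:10, timeAxisMs = 0:9), "baseline")
})

test_that("visual field classification follows the direction sign", {
  expect_equal(classifyField(siteGeometry(5, 10)), "upper")
  expect_equal(classifyField(siteGeometry(5, -10)), "lower")
  expect_error(siteGeometry(5, 0), "non-zero")
  expect_error(siteGeometry(-1, 10), "positive")
  expect_error(siteGeometry(5, 95))
})

fakeMeasurements <- function(dirs, values = NULL, ecc = 8) {
  n <- length(dirs)
  data.frame(session_id = sprintf("s%03d", seq_len(n)),
             signal = "lfp", window = "PERISACC",
             field = ifelse(dirs > 0, "upper", "lower"),
             eccentricity_deg = rep_len(ecc, n), direction_deg = dirs,
             value = if (is.null(values)) rnorm(n) else values,
             stringsAsFactors = FALSE)
}

test_that("direction bins overlap and never straddle the horizon", {
  m <- fakeMeasurements(c(10, -10))
  mem <- directionBinMembership(m)
  up <- mem[mem$field == "upper", ]
  expect_setequal(up$lo_deg, c(0, 10))   # +10 deg joins [0,20) and [10,30)
  lo <- mem[mem$field == "lower", ]
  expect_setequal(lo$lo_deg, c(0, 10))
  expect_true(all(mem$lo_deg >= 0))

  # membership is exhaustive and double for interior non-edge directions
  set.seed(4)
  dirs <- runif(200, 5, 85)
  counts <- vapply(dirs, function(d)
    nrow(directionBinMembership(fakeMeasurements(d))), numeric(1))
  expect_true(all(counts >= 1))
  interior <- dirs > 10 & dirs < 80 & (dirs %% 10 != 0)
  expect_true(all(counts[interior] == 2))
})

test_that("direction bins honor the minimum-count rule", {
  m9 <- fakeMeasurements(rep(15, 9))
  expect_equal(nrow(directionBins(m9, minN = 10)), 0)
  m12 <- fakeMeasurements(rep(15, 12))
  b <- directionBins(m12, minN = 10)
  expect_equal(nrow(b), 2)   # [0,20) and [10,30), both with n = 12
  expect_equal(b$n, c(12, 12))
  expect_equal(b$mean, rep(mean(m12$value), 2))
})

test_that("binning is invariant to the order of the measurement rows", {
  set.seed(11)
  m <- fakeMeasurements(c(runif(30, 5, 85), -runif(30, 5, 85)))
  b1 <- directionBins(m, minN = 3)
  b2 <- directionBins(m[sample(nrow(m)), ], minN = 3)
  expect_equal(b1, b2)
})

test_that("eccentricity bins use the default four-bin edges", {
  m <- fakeMeasurements(rep(c(10, -10), 4), values = 1:8,
                        ecc = c(1.5, 1.5, 3, 3, 7, 7, 15, 15))
  b <- eccentricityBins(m)
  expect_equal(sort(unique(b$lo_deg)), c(0, 2, 5, 10))
  expect_equal(b$bin_label[b$lo_deg == 0][1], "[0,2)")
  expect_equal(nrow(b), 8)   # 4 bins x 2 fields
  expect_true(all(b$n == 1))
  # out-of-range eccentricities are not binned
  m2 <- fakeMeasurements(c(10, -10), ecc = c(40, 3))
  expect_message(b2 <- eccentricityBins(m2), "not binned")
  expect_equal(sum(b2$n), 1)
})

test_that("empty field-by-bin cells are dropped from the two-way ANOVA", {
  # no upper-field session below 2 deg eccentricity
  set.seed(12)
  ecc <- c(runif(40, 2, 25), runif(5, 0.5, 1.9), runif(35, 2, 25))
  dirs <- c(runif(40, 5, 85), -runif(40, 5, 85))
  m <- fakeMeasurements(dirs, ecc = ecc)
  res <- fieldByBinAnova(m, "eccentricity")
  # the [0,2) bin exists only in the lower field, so b = 3 bins remain and
  # those 5 lower-field sessions are excluded: N = 75
  expect_equal(res[[2]]@df[1], 2)   # 3 bins - 1
  expect_equal(sum(res[[1]]@nPerGroup), 75)
  expect_equal(res[[1]]@df[2], 75 - 1 - 1 - 2)
})

test_that("asymmetry ratios come from the group means", {
  expect_equal(asymmetryRatio(c(-2.7, -2.7), c(-1, -1)), 2.7)
  expect_equal(asymmetryRatio(c(5, 7), c(5, 7)), 1)
  expect_error(asymmetryRatio(c(1, 2), c(-1, 1)), "zero")
})

test_that("noiseless sessions recover the injected gain ratio exactly", {
  # delay plateau off so the peri-saccadic window holds only the peri
  # kernel; same seed gives identical event timelines in both fields, so
  # the window-integration factor cancels exactly
  cfg <- noiselessConfig(fsHz = 1000, delayPeakUv = 0)
  for (seed in c(21, 22)) {
    su <- simulateSession("visual", siteGeometry(7, 30), 3, cfg, seed = seed)
    sl <- simulateSession("visual", siteGeometry(7, -30), 3, cfg, seed = seed)
    m <- sessionMeasurements(list(su, sl), "lfp", "PERISACC")
    r <- asymmetryRatio(m$value[m$field == "upper"],
                        m$value[m$field == "lower"])
    expect_equal(r, 2.7, tolerance = 1e-12)
  }
})
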