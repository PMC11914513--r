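test_that("trial event timelines respect the task design", {
  cfg <- generatorConfig()
  evm <- sampleTrialEvents(50, "memory", cfg, seed = 1)
  expect_equal(evm$target_off_s - evm$target_on_s, rep(0.050, 50))
  expect_true(all(evm$go_s - evm$target_on_s >= 0.3 - 1e-12))
  expect_true(all(evm$go_s - evm$target_on_s <= 1.0 + 1e-12))

  evv <- sampleTrialEvents(50, "visual", cfg, seed = 2)
  expect_true(all(evv$go_s - evv$target_on_s >= 0.5 - 1e-12))
  expect_true(all(evv$go_s - evv$target_on_s <= 1.0 + 1e-12))
  # visual target stays on until the trial ends
  expect_true(all(evv$target_off_s >= evv$saccade_off_s))
  # fixation durations within range, saccade latency within range
  expect_true(all(evv$target_on_s - evv$fixation_on_s >= 0.3 - 1e-12))
  expect_true(all(evv$target_on_s - evv$fixation_on_s <= 1.0 + 1e-12))
  expect_true(all(evv$saccade_on_s - evv$go_s >= 0.15 - 1e-12))
  expect_true(all(evv$saccade_on_s - evv$go_s <= 0.20 + 1e-12))
  expect_equal(evv$saccade_off_s - evv$saccade_on_s, rep(0.040, 50))
  # strict ordering per trial
  expect_true(all(evv$fixation_on_s < evv$target_on_s &
                    evv$target_on_s < evv$go_s &
                    evv$go_s < evv$saccade_on_s &
                    evv$saccade_on_s < evv$saccade_off_s))
})

test_that("collapsed timing ranges force deterministic delays", {
  cfg <- generatorConfig(fixationRangeMs = c(500, 500))
  ev <- sampleTrialEvents(1, "visual", cfg, seed = 7)
  expect_equal(ev$target_on_s - ev$fixation_on_s, 0.500)
})

test_that("invalid task or degenerate range is rejected", {
  expect_error(sampleTrialEvents(2, "antisaccade", generatorConfig()))
  expect_error(generatorConfig(fixationRangeMs = c(1000, 300)), "degenerate")
  expect_error(generatorConfig(periSdMs = -1), "positive")
})

test_that("LFP component kernels have the documented shape and gains", {
  cfg <- generatorConfig(stimPeakUv = 1)
  # unit-amplitude stimulus kernel peaks at -1 at its latency
  expect_equal(lfpComponentKernel("stimulus", "visual", 60, cfg, gain = 1), -1)
  t <- seq(-100, 200)
  k <- lfpComponentKernel("stimulus", "visual", t, cfg, gain = 1)
  expect_equal(t[which.min(k)], 60)

  # delay plateau: negative for visual, positive for memory
  cfg2 <- generatorConfig()
  mid <- 400   # well inside a 600 ms delay plateau
  kv <- lfpComponentKernel("delay", "visual", mid, cfg2, 1, goDelayMs = 600)
  km <- lfpComponentKernel("delay", "memory", mid, cfg2, 1, goDelayMs = 600)
  expect_lt(kv, 0)
  expect_gt(km, 0)
  expect_equal(kv, -km)

  # peri-saccadic upper/lower peak ratio equals the configured 2.7
  up <- lfpComponentKernel("perisaccadic", "visual", 25, cfg2,
                           cfg2$periGain[["upper"]])
  lo <- lfpComponentKernel("perisaccadic", "visual", 25, cfg2,
                           cfg2$periGain[["lower"]])
  expect_equal(up / lo, 2.7)
  expect_error(lfpComponentKernel("delay", "visual", 0, cfg2, 1), "goDelayMs")
})

test_that("noiseless traces equal the deterministic kernel sum", {
  cfg <- noiselessConfig(fsHz = 2000)
  ev <- sampleTrialEvents(3, "visual", cfg, seed = 5)
  rec <- generateLfpTrial(ev, upperSite(), "visual", cfg)
  oracle <- kernelSumOracle(ev, upperSite(), "visual", cfg,
                            length(samples(rec)))
  expect_equal(samples(rec), oracle, tolerance = 1e-12)

  # upper vs lower peri-saccadic trough ratio on identical events (delay
  # plateau off so only the peri-saccadic component is present at the trough)
  cfgP <- noiselessConfig(fsHz = 2000, delayPeakUv = 0)
  recU <- generateLfpTrial(ev, upperSite(), "visual", cfgP)
  recL <- generateLfpTrial(ev, lowerSite(), "visual", cfgP)
  fs <- cfgP$fsHz
  i <- round((ev$saccade_on_s[2] + 0.025) * fs) + 1
  expect_equal(samples(recU)[i] / samples(recL)[i], 2.7, tolerance = 1e-9)

  # zero amplitudes give an all-zero trace
  cfg0 <- noiselessConfig(fsHz = 2000, stimPeakUv = 0, periPeakUv = 0,
                          delayPeakUv = 0)
  rec0 <- generateLfpTrial(ev, upperSite(), "visual", cfg0)
  expect_equal(max(abs(samples(rec0))), 0)
})

test_that("identical config and seed give identical sessions", {
  cfg <- generatorConfig(fsHz = 2000)
  s1 <- simulateSession("memory", upperSite(), 3, cfg, seed = 9)
  s2 <- simulateSession("memory", upperSite(), 3, cfg, seed = 9)
  expect_identical(samples(s1@raw), samples(s2@raw))
  expect_identical(spikeTimes(s1@spikes), spikeTimes(s2@spikes))
  expect_identical(s1@events, s2@events)
})

test_that("homogeneous-rate spike counts match the Poisson expectation", {
  # all bursts off: thinning must reproduce a constant 100 sp/s process
  cfg <- generatorConfig(fsHz = 1000, baselineRate = 100, visualBurstPeak = 0,
                         delayRate = 0, motorBurstPeak = 0)
  ev <- sampleTrialEvents(1, "visual", cfg, seed = 1)
  dur <- 2.0
  counts <- vapply(1:60, function(s) {
    length(spikeTimes(generateSpikeTrain(ev, upperSite(), cfg,
                                         durationS = dur, seed = s)))
  }, numeric(1))
  lambda <- 100 * dur
  # mean count within the 99% band of the mean of 60 Poisson draws
  se <- sqrt(lambda / 60)
  expect_lt(abs(mean(counts) - lambda), 2.6 * se)
  # dispersion consistent with Poisson (variance/mean not wildly off 1)
  expect_gt(var(counts) / mean(counts), 0.5)
  expect_lt(var(counts) / mean(counts), 2.0)
})

test_that("zero rate gives an empty train; spikes are sorted and in range", {
  cfg0 <- generatorConfig(fsHz = 1000, baselineRate = 0, visualBurstPeak = 0,
                          delayRate = 0, motorBurstPeak = 0)
  ev <- sampleTrialEvents(1, "visual", cfg0, seed = 2)
  st <- generateSpikeTrain(ev, upperSite(), cfg0, seed = 3)
  expect_length(spikeTimes(st), 0)

  cfg <- generatorConfig(fsHz = 1000)
  st2 <- generateSpikeTrain(ev, lowerSite(), cfg, seed = 4)
  tt <- spikeTimes(st2)
  expect_false(is.unsorted(tt, strictly = TRUE))
  expect_true(all(tt >= 0 & tt <= recordingDuration(st2)))
})

test_that("motor bursts are weaker in the upper visual field", {
  cfg <- generatorConfig(fsHz = 1000)
  ev <- sampleTrialEvents(100, "visual", cfg, seed = 11)
  inWindow <- function(st) {
    tt <- spikeTimes(st)
    mean(vapply(ev$saccade_on_s, function(s)
      sum(tt >= s & tt < s + 0.05), numeric(1))) / 0.05
  }
  rUp <- inWindow(generateSpikeTrain(ev, upperSite(), cfg, seed = 21))
  rLo <- inWindow(generateSpikeTrain(ev, lowerSite(), cfg, seed = 22))
  expect_lt(rUp, rLo)
})

test_that("negative rate configurations are refused", {
  cfg <- generatorConfig(fsHz = 1000)
  cfg$baselineRate <- -5   # bypass constructor validation on purpose
  ev <- sampleTrialEvents(1, "visual", generatorConfig(fsHz = 1000), seed = 1)
  expect_error(suppressWarnings(generateSpikeTrain(ev, upperSite(), cfg,
                                                   seed = 1)))
})

test_that("generateDataset writes reproducible bundles with drawn geometry", {
  cfg <- noiselessConfig(fsHz = 2000)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  ds1 <- generateDataset(2, 3, 4, "visual", cfg, outPath = d1, masterSeed = 0,
                         keepInMemory = FALSE)
  ds2 <- generateDataset(2, 3, 4, "visual", cfg, outPath = d2, masterSeed = 0,
                         keepInMemory = FALSE)
  expect_equal(nrow(ds1$manifest), 5)
  expect_equal(sum(ds1$manifest$field == "upper"), 2)
  for (i in seq_len(5)) {
    ev <- utils::read.csv(file.path(ds1$manifest$path[i], "events.csv"))
    expect_equal(nrow(ev), 4)
  }
  # byte-identical across two runs with the same master seed
  expect_identical(ds1$manifest$checksum, ds2$manifest$checksum)
  # geometry ranges
  expect_true(all(abs(ds1$manifest$direction_deg) >= 5 &
                    abs(ds1$manifest$direction_deg) <= 85))
  expect_true(all(ds1$manifest$eccentricity_deg >= 2 &
                    ds1$manifest$eccentricity_deg <= 25))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("memory-task bundles carry the 50 ms flash", {
  cfg <- noiselessConfig(fsHz = 2000)
  ds <- generateDataset(1, 1, 1, "memory", cfg, masterSeed = 5)
  for (s in ds$sessions)
    expect_equal(s@events$target_off_s - s@events$target_on_s, 0.050)
})

test_that("pink noise has a 1/f periodogram and the requested scale", {
  set.seed(42)
  x <- pinkNoise(2^17, sd = 10)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 1), plot = FALSE,
                          taper = 0, spans = 31)
  sel <- sp$freq > 1e-4 & sp$freq < 0.3
  slope <- unname(stats::coef(stats::lm(log10(sp$spec[sel]) ~
                                          log10(sp$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.2)
  sds <- replicate(10, stats::sd(pinkNoise(2^15, sd = 10)))
  expect_lt(abs(mean(sds) - 10), 2)
})

test_that("line-noise power is concentrated at the line frequencies", {
  cfg <- generatorConfig(fsHz = 8000, pinkSdUv = 0, whiteSdUv = 0,
                         stimPeakUv = 0, periPeakUv = 0, delayPeakUv = 0)
  ev <- sampleTrialEvents(1, "visual", cfg, seed = 3)
  rec <- generateLfpTrial(ev, upperSite(), "visual", cfg, durationS = 4,
                          seed = 3)
  sp <- stats::spec.pgram(stats::ts(samples(rec), frequency = 8000),
                          plot = FALSE, taper = 0, detrend = FALSE)
  near <- rowSums(vapply(c(50, 100, 150), function(f)
    abs(sp$freq - f) <= 1, logical(length(sp$freq)))) > 0
  expect_gt(sum(sp$spec[near]) / sum(sp$spec), 0.99)
})

test_that("session-mean noise shrinks as sigma over sqrt(trials)", {
  # direct 1 kHz generation; pure-noise config so deviation = noise mean
  cfg <- directConfig(stimPeakUv = 0, periPeakUv = 0, delayPeakUv = 0)
  nT <- 25
  sigma <- sqrt(cfg$pinkSdUv^2 + cfg$whiteSdUv^2)
  rms <- vapply(1:8, function(s) {
    b <- simulateSession("visual", upperSite(), nT, cfg, seed = 100 + s)
    m <- sessionMean(buildEpochMatrix(b, "lfp", "saccade_on", c(-200, 200)))
    sqrt(mean(m^2))
  }, numeric(1))
  expect_lt(mean(rms), 3 * sigma / sqrt(nT))
  expect_gt(mean(rms), sigma / sqrt(nT) / 3)
})
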