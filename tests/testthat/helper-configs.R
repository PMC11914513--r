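# shared generator configurations for the tests

# no noise at all: traces are the deterministic kernel sums
noiselessConfig <- function(fsHz = 2000, ...) {
  generatorConfig(fsHz = fsHz, pinkSdUv = 0, whiteSdUv = 0,
                  lineAmpUv = c(0, 0, 0), ...)
}

# 1 kHz generation: analysis-ready traces without the conditioning chain
directConfig <- function(...) {
  generatorConfig(fsHz = 1000, lineAmpUv = c(0, 0, 0), ...)
}

upperSite <- function() siteGeometry(5, 10)
lowerSite <- function() siteGeometry(5, -10)

# deterministic kernel-sum oracle: evaluates the component kernels over each
# trial's span on the sample grid, independently of the generator's internals
kernelSumOracle <- function(events, geometry, task, config, nSamples) {
  fs <- config$fsHz
  g <- function(gain) {
    d <- direction(geometry)
    if (config$fieldModel == "step") {
      if (d > 0) gain[["upper"]] else gain[["lower"]]
    } else gain[["lower"]] + (gain[["upper"]] - gain[["lower"]]) * (d + 90) / 180
  }
  out <- numeric(nSamples)
  ends <- c(events$fixation_on_s[-1],
            events$saccade_off_s[nrow(events)] + config$postTrialS)
  for (i in seq_len(nrow(events))) {
    i0 <- max(0L, as.integer(floor(events$fixation_on_s[i] * fs + 1e-9)))
    i1 <- min(nSamples - 1L, as.integer(floor(ends[i] * fs + 1e-9)) - 1L)
    idx <- i0:i1
    tS <- idx / fs
    tStim <- (tS - events$target_on_s[i]) * 1000
    tPeri <- (tS - events$saccade_on_s[i]) * 1000
    goDelay <- (events$go_s[i] - events$target_on_s[i]) * 1000
    s <- if (task == "visual") -1 else 1
    out[idx + 1] <- out[idx + 1] +
      (-config$stimPeakUv * g(config$stimGain) *
         exp(-(tStim - config$stimLatencyMs)^2 / (2 * config$stimSdMs^2))) +
      (-config$periPeakUv * g(config$periGain) *
         exp(-(tPeri - config$periLatencyMs)^2 / (2 * config$periSdMs^2))) +
      (s * config$delayPeakUv * g(config$delayGain) /
         (1 + exp(-(tStim - config$delayOnsetMs) / config$delayTauMs)) /
         (1 + exp((tStim - goDelay - config$delayOffsetAfterGoMs) /
                    config$delayTauMs)))
  }
  out
}
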