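#' Generator configuration for synthetic saccade sessions
#'
#' Bundles every ground-truth parameter of the synthetic session generator:
#' LFP component kernels (stimulus-evoked, delay-period, peri-saccadic) with
#' their upper/lower visual-field gains, noise levels (pink, white, mains),
#' spike-rate parameters, and task timing ranges. The defaults encode the
#' study conditions the pipeline is meant to recover: a peri-saccadic LFP
#' deflection ~2.7x larger (in absolute value) in the upper visual field, a
#' stimulus-evoked deflection ~2.5x larger in the upper field, visual spike
#' bursts stronger in the upper field, and motor bursts weaker in the upper
#' field, all changing as a step across the horizontal meridian.
#'
#' @param fsHz wideband sampling rate, Hz.
#' @param stimLatencyMs,stimSdMs,stimPeakUv stimulus-evoked LFP kernel:
#'   latency to (negative) peak from target onset, Gaussian SD, and unit-gain
#'   peak magnitude in microvolts.
#' @param stimGain named upper/lower field gains of the stimulus kernel.
#' @param periLatencyMs,periSdMs,periPeakUv peri-saccadic LFP kernel: latency
#'   to peak from saccade onset, SD, unit-gain peak magnitude.
#' @param periGain named upper/lower field gains of the peri-saccadic kernel.
#' @param delayOnsetMs delay-period plateau onset, ms after target onset.
#' @param delayOffsetAfterGoMs plateau release, ms after the go signal.
#' @param delayTauMs logistic rise/fall time constant of the plateau, ms.
#' @param delayPeakUv unit-gain plateau magnitude, microvolts. The plateau is
#'   negative for the visual task (sustained visual drive) and positive for
#'   the memory task (working-memory positivity).
#' @param delayGain named upper/lower field gains of the delay plateau.
#' @param pinkSdUv,whiteSdUv per-sample SD of the 1/f and white noise, uV.
#' @param lineFreqsHz,lineAmpUv mains interference frequencies and amplitudes.
#' @param baselineRate baseline firing rate, spikes/s.
#' @param visualBurstPeak,visualBurstGain,visualBurstLatencyMs,visualBurstSdMs
#'   visual burst: unit-gain peak rate, field gains (stronger upper), latency
#'   from target onset and Gaussian SD.
#' @param delayRate field-independent sustained delay firing rate, spikes/s.
#' @param motorBurstPeak,motorBurstGain,motorBurstLatencyMs,motorBurstSdMs
#'   motor burst: unit-gain peak rate, field gains (weaker upper), latency
#'   from saccade onset and Gaussian SD.
#' @param fixationRangeMs fixation duration range (uniform), ms.
#' @param visualDelayRangeMs target-on to go range for the visual task, ms.
#' @param memoryDelayRangeMs target-on to go range for the memory task, ms.
#' @param saccadeLatencyRangeMs go to saccade-onset range, ms.
#' @param saccadeDurationMs fixed saccade duration, ms.
#' @param flashDurationMs memory-task target flash duration, ms.
#' @param leadInS,postTrialS,tailS session layout: recording lead-in before
#'   the first trial, post-saccade margin per trial, and tail after the last
#'   trial, seconds.
#' @param fieldModel "step" (gains switch at the horizontal meridian, the
#'   study model) or "linear" (gains interpolate linearly in direction, a
#'   control model without a discontinuity).
#' @param hardwareBandpass if TRUE, emulate the acquisition hardware band-pass
#'   (0.7 Hz to 6 kHz) on the generated wideband trace. Off by default: the
#'   software conditioning chain dominates at analysis bandwidth.
#' @return A classed list of generator parameters.
#' @examples
#' cfg <- generatorConfig()
#' cfg$periGain[["upper"]] / cfg$periGain[["lower"]]  # 2.7
#' @export
generatorConfig <- function(fsHz = 40000,
                            stimLatencyMs = 60, stimSdMs = 15, stimPeakUv = 60,
                            stimGain = c(upper = 2.5, lower = 1.0),
                            periLatencyMs = 25, periSdMs = 20, periPeakUv = 80,
                            periGain = c(upper = 2.7, lower = 1.0),
                            delayOnsetMs = 150, delayOffsetAfterGoMs = 100,
                            delayTauMs = 30, delayPeakUv = 30,
                            delayGain = c(upper = 1.5, lower = 1.0),
                            pinkSdUv = 15, whiteSdUv = 5,
                            lineFreqsHz = c(50, 100, 150),
                            lineAmpUv = c(20, 10, 5),
                            baselineRate = 10,
                            visualBurstPeak = 100,
                            visualBurstGain = c(upper = 1.5, lower = 1.0),
                            visualBurstLatencyMs = 50, visualBurstSdMs = 15,
                            delayRate = 20,
                            motorBurstPeak = 200,
                            motorBurstGain = c(upper = 0.7, lower = 1.0),
                            motorBurstLatencyMs = 20, motorBurstSdMs = 15,
                            fixationRangeMs = c(300, 1000),
                            visualDelayRangeMs = c(500, 1000),
                            memoryDelayRangeMs = c(300, 1000),
                            saccadeLatencyRangeMs = c(150, 200),
                            saccadeDurationMs = 40,
                            flashDurationMs = 50,
                            leadInS = 0.5, postTrialS = 0.3, tailS = 0.5,
                            fieldModel = c("step", "linear"),
                            hardwareBandpass = FALSE) {
  fieldModel <- match.arg(fieldModel)
  cfg <- list(fsHz = fsHz,
              stimLatencyMs = stimLatencyMs, stimSdMs = stimSdMs,
              stimPeakUv = stimPeakUv, stimGain = stimGain,
              periLatencyMs = periLatencyMs, periSdMs = periSdMs,
              periPeakUv = periPeakUv, periGain = periGain,
              delayOnsetMs = delayOnsetMs,
              delayOffsetAfterGoMs = delayOffsetAfterGoMs,
              delayTauMs = delayTauMs, delayPeakUv = delayPeakUv,
              delayGain = delayGain,
              pinkSdUv = pinkSdUv, whiteSdUv = whiteSdUv,
              lineFreqsHz = lineFreqsHz, lineAmpUv = lineAmpUv,
              baselineRate = baselineRate,
              visualBurstPeak = visualBurstPeak,
              visualBurstGain = visualBurstGain,
              visualBurstLatencyMs = visualBurstLatencyMs,
              visualBurstSdMs = visualBurstSdMs,
              delayRate = delayRate,
              motorBurstPeak = motorBurstPeak,
              motorBurstGain = motorBurstGain,
              motorBurstLatencyMs = motorBurstLatencyMs,
              motorBurstSdMs = motorBurstSdMs,
              fixationRangeMs = fixationRangeMs,
              visualDelayRangeMs = visualDelayRangeMs,
              memoryDelayRangeMs = memoryDelayRangeMs,
              saccadeLatencyRangeMs = saccadeLatencyRangeMs,
              saccadeDurationMs = saccadeDurationMs,
              flashDurationMs = flashDurationMs,
              leadInS = leadInS, postTrialS = postTrialS, tailS = tailS,
              fieldModel = fieldModel,
              hardwareBandpass = isTRUE(hardwareBandpass))
  class(cfg) <- "GeneratorConfig"
  validateGeneratorConfig(cfg)
  cfg
}

validateGeneratorConfig <- function(cfg) {
  pos <- c("fsHz", "stimSdMs", "periSdMs", "delayTauMs", "visualBurstSdMs",
           "motorBurstSdMs", "saccadeDurationMs", "flashDurationMs")
  for (f in pos)
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("generator parameter '%s' must be positive", f))
  nonneg <- c("stimPeakUv", "periPeakUv", "delayPeakUv", "pinkSdUv",
              "whiteSdUv", "baselineRate", "visualBurstPeak", "delayRate",
              "motorBurstPeak")
  for (f in nonneg)
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("generator parameter '%s' must be finite and >= 0", f))
  for (f in c("stimGain", "periGain", "delayGain", "visualBurstGain",
              "motorBurstGain")) {
    g <- cfg[[f]]
    if (!all(c("upper", "lower") %in% names(g)) || any(!is.finite(g)) ||
        any(g < 0))
      stop(sprintf("'%s' must be finite, non-negative and named upper/lower", f))
  }
  for (f in c("fixationRangeMs", "visualDelayRangeMs", "memoryDelayRangeMs",
              "saccadeLatencyRangeMs")) {
    r <- cfg[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0)
      stop(sprintf("degenerate range for '%s' (need 0 <= min <= max)", f))
  }
  if (length(cfg$lineFreqsHz) != length(cfg$lineAmpUv))
    stop("lineFreqsHz and lineAmpUv must have equal length")
  invisible(cfg)
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat("GeneratorConfig:",
      sprintf("fs = %g Hz, field model = %s", x$fsHz, x$fieldModel), "\n")
  cat(sprintf("  peri-saccadic gain ratio %.2f, stimulus gain ratio %.2f\n",
              x$periGain[["upper"]] / x$periGain[["lower"]],
              x$stimGain[["upper"]] / x$stimGain[["lower"]]))
  cat(sprintf("  noise: pink %g uV, white %g uV, mains %s uV at %s Hz\n",
              x$pinkSdUv, x$whiteSdUv, paste(x$lineAmpUv, collapse = "/"),
              paste(x$lineFreqsHz, collapse = "/")))
  invisible(x)
}

#' Null-asymmetry variant of a generator configuration
#'
#' Returns `config` with all upper/lower field gains set equal (to the lower
#' field gain), removing every visual-field asymmetry. Used for Type-I error
#' calibration of the group statistics.
#'
#' @param config a [generatorConfig()].
#' @return The modified configuration.
#' @export
nullGeneratorConfig <- function(config = generatorConfig()) {
  for (f in c("stimGain", "periGain", "delayGain", "visualBurstGain",
              "motorBurstGain"))
    config[[f]]["upper"] <- config[[f]]["lower"]
  config
}

## field gain of one LFP/rate component for a site, honoring the field model
fieldGain <- function(gain, geometry, fieldModel = "step") {
  d <- direction(geometry)
  if (fieldModel == "step") {
    unname(if (d > 0) gain[["upper"]] else gain[["lower"]])
  } else {
    unname(gain[["lower"]] +
             (gain[["upper"]] - gain[["lower"]]) * (d + 90) / 180)
  }
}

#' Sample per-trial event timelines
#'
#' Draws `n` trials of either the delayed visually-guided or the memory-guided
#' saccade task and lays them out sequentially in recording time. Fixation
#' lasts Uniform(300, 1000) ms; the target-to-go delay is Uniform(500, 1000)
#' ms for the visual task and Uniform(300, 1000) ms for the memory task;
#' saccade latency after the go signal is Uniform(150, 200) ms and saccade
#' duration is fixed at 40 ms (all configurable). In the memory task the
#' target is flashed for exactly 50 ms; in the visual task it stays visible
#' until the end of the trial.
#'
#' @param n number of trials.
#' @param task "visual" or "memory".
#' @param config a [generatorConfig()].
#' @param seed optional integer seed; when NULL the current RNG state is used.
#' @return A data.frame with columns `trial_id`, `fixation_on_s`,
#'   `target_on_s`, `target_off_s`, `go_s`, `saccade_on_s`, `saccade_off_s`
#'   (seconds from recording start).
#' @examples
#' ev <- sampleTrialEvents(5, "memory", generatorConfig(), seed = 1)
#' ev$target_off_s - ev$target_on_s   # all 0.050
#' @export
sampleTrialEvents <- function(n, task = c("visual", "memory"),
                              config = generatorConfig(), seed = NULL) {
  task <- match.arg(task)
  validateGeneratorConfig(config)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  fix <- runif(n, config$fixationRangeMs[1], config$fixationRangeMs[2]) / 1000
  delayRange <- if (task == "visual") config$visualDelayRangeMs else
    config$memoryDelayRangeMs
  del <- runif(n, delayRange[1], delayRange[2]) / 1000
  lat <- runif(n, config$saccadeLatencyRangeMs[1],
               config$saccadeLatencyRangeMs[2]) / 1000
  durS <- config$saccadeDurationMs / 1000
  trialLen <- fix + del + lat + durS + config$postTrialS
  start <- config$leadInS + c(0, cumsum(trialLen))[seq_len(n)]
  fixationOn <- start
  targetOn <- fixationOn + fix
  go <- targetOn + del
  saccadeOn <- go + lat
  saccadeOff <- saccadeOn + durS
  targetOff <- if (task == "memory") targetOn + config$flashDurationMs / 1000
  else start + trialLen
  data.frame(trial_id = seq_len(n),
             fixation_on_s = fixationOn,
             target_on_s = targetOn,
             target_off_s = targetOff,
             go_s = go,
             saccade_on_s = saccadeOn,
             saccade_off_s = saccadeOff)
}

#' LFP component kernels
#'
#' Deterministic voltage paths of the three LFP components, evaluated on a
#' time axis relative to the component's aligning event. The stimulus-evoked
#' component is a negative Gaussian deflection peaking `stimLatencyMs` after
#' target onset; the peri-saccadic component a negative Gaussian peaking
#' `periLatencyMs` after saccade onset; the delay component a logistic ramp
#' to a sustained plateau from `delayOnsetMs` after target onset until
#' `delayOffsetAfterGoMs` after the go signal, negative for the visual task
#' and positive for the memory task.
#'
#' @param component "stimulus", "delay" or "perisaccadic".
#' @param task "visual" or "memory" (the delay plateau sign depends on it).
#' @param tMs numeric time axis in ms relative to the aligning event (target
#'   onset for stimulus and delay, saccade onset for perisaccadic).
#' @param config a [generatorConfig()].
#' @param gain multiplicative field gain applied to the configured peak.
#' @param goDelayMs for the delay component, the go time in ms after target
#'   onset (defines where the plateau is released).
#' @return Numeric voltage path in microvolts, same length as `tMs`.
#' @examples
#' t <- seq(-50, 150, by = 1)
#' k <- lfpComponentKernel("stimulus", "visual", t, generatorConfig(), gain = 1)
#' t[which.min(k)]   # 60 ms latency to the negative peak
#' @export
lfpComponentKernel <- function(component = c("stimulus", "delay", "perisaccadic"),
                               task = c("visual", "memory"),
                               tMs, config = generatorConfig(), gain = 1,
                               goDelayMs = NULL) {
  component <- match.arg(component)
  task <- match.arg(task)
  switch(component,
    stimulus = -config$stimPeakUv * gain *
      exp(-(tMs - config$stimLatencyMs)^2 / (2 * config$stimSdMs^2)),
    perisaccadic = -config$periPeakUv * gain *
      exp(-(tMs - config$periLatencyMs)^2 / (2 * config$periSdMs^2)),
    delay = {
      if (is.null(goDelayMs))
        stop("goDelayMs is required for the delay component")
      s <- if (task == "visual") -1 else 1
      rise <- 1 / (1 + exp(-(tMs - config$delayOnsetMs) / config$delayTauMs))
      fall <- 1 / (1 + exp((tMs - goDelayMs - config$delayOffsetAfterGoMs) /
                             config$delayTauMs))
      s * config$delayPeakUv * gain * rise * fall
    })
}

## deterministic kernel sum for a set of trials on the absolute sample grid
## [0, nSamples): adds event-locked components trial by trial over each
## trial's own span (trials tile the recording, so no double counting)
kernelSumOnGrid <- function(events, geometry, config, task, nSamples, fsHz) {
  out <- numeric(nSamples)
  gStim <- fieldGain(config$stimGain, geometry, config$fieldModel)
  gPeri <- fieldGain(config$periGain, geometry, config$fieldModel)
  gDelay <- fieldGain(config$delayGain, geometry, config$fieldModel)
  ends <- c(events$fixation_on_s[-1],
            events$saccade_off_s[nrow(events)] + config$postTrialS)
  for (i in seq_len(nrow(events))) {
    i0 <- max(0L, as.integer(floor(events$fixation_on_s[i] * fsHz + 1e-9)))
    i1 <- min(nSamples - 1L, as.integer(floor(ends[i] * fsHz + 1e-9)) - 1L)
    if (i1 < i0) next
    idx <- i0:i1
    tS <- idx / fsHz
    tStimMs <- (tS - events$target_on_s[i]) * 1000
    tPeriMs <- (tS - events$saccade_on_s[i]) * 1000
    goDelayMs <- (events$go_s[i] - events$target_on_s[i]) * 1000
    out[idx + 1L] <- out[idx + 1L] +
      lfpComponentKernel("stimulus", task, tStimMs, config, gStim) +
      lfpComponentKernel("perisaccadic", task, tPeriMs, config, gPeri) +
      lfpComponentKernel("delay", task, tStimMs, config, gDelay,
                         goDelayMs = goDelayMs)
  }
  out
}

#' Pink (1/f) noise
#'
#' Synthesizes Gaussian noise with a 1/f power spectrum by filtering white
#' Gaussian noise through a cascade of first-order pole/zero sections whose
#' corner frequencies are spaced geometrically (two sections per decade from
#' 1e-5 to 0.4 in normalized frequency), the standard "pinking filter"
#' construction giving -10 dB/decade amplitude with small ripple. The output
#' is rescaled by the cascade's exact impulse-response energy so the expected
#' per-sample SD equals `sd` (no data-dependent normalization, which keeps
#' the noise jointly Gaussian and the generator linear).
#'
#' @param n number of samples.
#' @param sd target per-sample standard deviation.
#' @return Numeric vector of length `n` with (expected) SD `sd`.
#' @examples
#' x <- pinkNoise(4096, sd = 2)
#' @export
pinkNoise <- function(n, sd = 1) {
  if (n < 2 || sd == 0) return(numeric(n))
  as.numeric(pinkNoiseMatrix(n, 1L, sd))
}

## pinking-cascade coefficients (normalized frequency): poles every half
## decade, zeros a quarter decade above, giving ~1/sqrt(f) amplitude
pinkCascade <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fp <- 10^seq(-5, log10(0.35), by = 0.5)
    fz <- fp * 10^0.25
    zp <- exp(-2 * pi * fp)
    zz <- exp(-2 * pi * fz)
    h <- .pinkCascadeCpp(matrix(c(1, numeric(2^18 - 1))), zz, zp)
    cache <<- list(zz = zz, zp = zp, energy = sum(h^2))
    cache
  }
})

## columns are independent pink-noise realizations
pinkNoiseMatrix <- function(n, m, sd = 1) {
  if (sd == 0 || n < 2) return(matrix(0, n, m))
  cas <- pinkCascade()
  w <- matrix(rnorm(n * m), n, m)
  .pinkCascadeCpp(w, cas$zz, cas$zp) * (sd / sqrt(cas$energy))
}

#' Generate the wideband LFP voltage of one or more trials
#'
#' Sums the event-locked LFP component kernels (stimulus-evoked locked to
#' target onset, delay plateau spanning the delay period, peri-saccadic
#' locked to saccade onset) over the recording grid and adds pink (1/f)
#' noise, white noise and mains interference at the configured line
#' frequencies with random phases. Field gains are selected by the sign of
#' the site's direction from horizontal (or interpolated linearly under the
#' "linear" field model).
#'
#' @param events a trial-event data.frame from [sampleTrialEvents()].
#' @param geometry the session's [siteGeometry()].
#' @param task "visual" or "memory".
#' @param config a [generatorConfig()].
#' @param durationS total recording duration in seconds; defaults to the end
#'   of the last trial plus the configured tail.
#' @param seed optional integer seed for the noise draws.
#' @return A [widebandRecording()] at `config$fsHz`, starting at time 0.
#' @examples
#' cfg <- generatorConfig(fsHz = 2000, pinkSdUv = 0, whiteSdUv = 0,
#'                        lineAmpUv = c(0, 0, 0))
#' ev <- sampleTrialEvents(1, "visual", cfg, seed = 2)
#' rec <- generateLfpTrial(ev, siteGeometry(5, 10), "visual", cfg)
#' @export
generateLfpTrial <- function(events, geometry, task = c("visual", "memory"),
                             config = generatorConfig(), durationS = NULL,
                             seed = NULL) {
  task <- match.arg(task)
  validObject(geometry)
  validateGeneratorConfig(config)
  if (!is.null(seed)) set.seed(seed)
  fs <- config$fsHz
  if (is.null(durationS))
    durationS <- events$saccade_off_s[nrow(events)] + config$postTrialS +
      config$tailS
  if (any(events$saccade_off_s + config$postTrialS > durationS + 1e-9))
    stop("events extend beyond the recording span")
  n <- as.integer(round(durationS * fs))
  x <- kernelSumOnGrid(events, geometry, config, task, n, fs)
  if (config$pinkSdUv > 0) x <- x + pinkNoise(n, config$pinkSdUv)
  if (config$whiteSdUv > 0) x <- x + rnorm(n, sd = config$whiteSdUv)
  if (any(config$lineAmpUv > 0))
    x <- x + lineNoise(n, fs, config$lineFreqsHz, config$lineAmpUv,
                       phases = runif(length(config$lineFreqsHz), 0, 2 * pi))
  rec <- widebandRecording(x, fsHz = fs, t0S = 0)
  if (config$hardwareBandpass) rec <- applyHardwareBandpass(rec)
  rec
}

#' Instantaneous firing-rate function of the generator
#'
#' Evaluates the ground-truth firing rate (spikes/s) at arbitrary times:
#' baseline, a visual burst after target onset (stronger in the upper field),
#' a field-independent sustained delay rate, and a motor burst spanning
#' saccade onset (weaker in the upper field).
#'
#' @param tS numeric times in seconds from recording start.
#' @inheritParams generateLfpTrial
#' @return Numeric rate vector, spikes/s.
#' @export
firingRateFunction <- function(tS, events, geometry,
                               config = generatorConfig()) {
  r <- rep(config$baselineRate, length(tS))
  gVis <- fieldGain(config$visualBurstGain, geometry, config$fieldModel)
  gMot <- fieldGain(config$motorBurstGain, geometry, config$fieldModel)
  for (i in seq_len(nrow(events))) {
    tVisMs <- (tS - events$target_on_s[i]) * 1000
    tMotMs <- (tS - events$saccade_on_s[i]) * 1000
    r <- r + config$visualBurstPeak * gVis *
      exp(-(tVisMs - config$visualBurstLatencyMs)^2 /
            (2 * config$visualBurstSdMs^2)) +
      config$motorBurstPeak * gMot *
      exp(-(tMotMs - config$motorBurstLatencyMs)^2 /
            (2 * config$motorBurstSdMs^2))
    inDelay <- tS >= events$target_on_s[i] + config$delayOnsetMs / 1000 &
      tS < events$go_s[i]
    r[inDelay] <- r[inDelay] + config$delayRate
  }
  r
}

#' Generate an inhomogeneous Poisson spike train by thinning
#'
#' Simulates spike times from the generator's rate function with the thinning
#' algorithm: candidate spikes are drawn from a homogeneous Poisson process at
#' a rate bounding the maximum of the rate function (evaluated on a 1 ms
#' grid), then accepted with probability rate(t)/bound.
#'
#' @inheritParams generateLfpTrial
#' @param durationS recording duration bounding the spike times.
#' @return A [spikeTrain()].
#' @examples
#' cfg <- generatorConfig(fsHz = 2000)
#' ev <- sampleTrialEvents(2, "visual", cfg, seed = 3)
#' st <- generateSpikeTrain(ev, siteGeometry(5, -20), cfg, seed = 3)
#' @export
generateSpikeTrain <- function(events, geometry, config = generatorConfig(),
                               durationS = NULL, seed = NULL) {
  validObject(geometry)
  validateGeneratorConfig(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(durationS))
    durationS <- events$saccade_off_s[nrow(events)] + config$postTrialS +
      config$tailS
  grid <- seq(0, durationS, by = 0.001)
  rGrid <- firingRateFunction(grid, events, geometry, config)
  if (min(rGrid) < 0)
    stop("negative firing rate in the generator rate function")
  rMax <- max(rGrid) * 1.05 + 1
  nCand <- rpois(1, rMax * durationS)
  if (nCand == 0) return(spikeTrain(numeric(0), durationS))
  cand <- sort(runif(nCand, 0, durationS))
  keep <- runif(nCand) < firingRateFunction(cand, events, geometry, config) / rMax
  times <- unique(cand[keep])
  spikeTrain(times, durationS)
}

#' Simulate one complete session in memory
#'
#' Draws the trial timeline, the wideband LFP and the spike train of a single
#' synthetic session. All randomness is governed by `seed`.
#'
#' @param task "visual" or "memory".
#' @param geometry the session's [siteGeometry()].
#' @param nTrials number of trials.
#' @param config a [generatorConfig()].
#' @param seed integer seed.
#' @param sessionId session identifier string.
#' @param spikes if FALSE, skip spike generation (LFP-only studies).
#' @return A [SessionBundle] with the raw wideband recording attached.
#' @examples
#' cfg <- generatorConfig(fsHz = 2000)
#' s <- simulateSession("visual", siteGeometry(5, 10), 3, cfg, seed = 11)
#' @export
simulateSession <- function(task = c("visual", "memory"), geometry, nTrials,
                            config = generatorConfig(), seed = 1L,
                            sessionId = sprintf("session_%06d", seed),
                            spikes = TRUE) {
  task <- match.arg(task)
  set.seed(seed)
  events <- sampleTrialEvents(nTrials, task, config)
  durationS <- events$saccade_off_s[nTrials] + config$postTrialS + config$tailS
  raw <- generateLfpTrial(events, geometry, task, config, durationS)
  st <- if (spikes) generateSpikeTrain(events, geometry, config, durationS)
  else spikeTrain(numeric(0), durationS)
  new("SessionBundle", sessionId = sessionId, task = task,
      geometry = geometry, events = events, spikes = st, raw = raw,
      lfp = NULL, rate = NULL, seed = as.numeric(seed),
      metadata = list(generator = "periLFP", fsHz = config$fsHz,
                      durationS = durationS))
}

## deterministic per-session seed fan-out from a master seed (kept < 2^31)
sessionSeeds <- function(masterSeed, n) {
  (as.numeric(masterSeed) %% 100000 * 20011 + 104729 * seq_len(n)) %%
    2147483647 + 1
}

#' Generate a dataset of session bundles
#'
#' Draws site geometries for `nUpper` upper-field and `nLower` lower-field
#' sessions (|direction| ~ Uniform(5, 85) deg signed by group, eccentricity ~
#' Uniform(2, 25) deg), simulates each session with a seed fanned out
#' deterministically from `masterSeed`, and either returns the bundles in
#' memory or writes them to disk as plain-directory bundles.
#'
#' @param nUpper,nLower number of upper/lower visual-field sessions.
#' @param trialsPerSession trials per session.
#' @param task "visual" or "memory".
#' @param config a [generatorConfig()].
#' @param outPath optional directory; when given, bundles are written with
#'   [writeBundle()] and the manifest gains their paths and checksums.
#' @param masterSeed integer master seed; the whole dataset is reproducible
#'   from it.
#' @param spikes generate spike trains (see [simulateSession()]).
#' @return A list with `manifest` (data.frame: session_id, task, field,
#'   eccentricity_deg, direction_deg, seed, and path/checksum when written)
#'   and `sessions` (list of [SessionBundle]; NULL elements when written to
#'   disk with `keepInMemory = FALSE`).
#' @param keepInMemory keep the simulated bundles in the returned list (set
#'   FALSE for large on-disk datasets).
#' @param processFUN optional function applied to each bundle right after
#'   simulation; its results replace the bundles in `sessions` and the
#'   bundle itself is discarded, keeping memory flat for large studies.
#' @examples
#' ds <- generateDataset(2, 2, 3, "visual", generatorConfig(fsHz = 2000),
#'                       masterSeed = 42)
#' ds$manifest
#' @export
generateDataset <- function(nUpper, nLower, trialsPerSession,
                            task = c("visual", "memory"),
                            config = generatorConfig(), outPath = NULL,
                            masterSeed = 1L, spikes = TRUE,
                            keepInMemory = is.null(outPath),
                            processFUN = NULL) {
  task <- match.arg(task)
  stopifnot(nUpper >= 1, nLower >= 1, trialsPerSession >= 1)
  n <- nUpper + nLower
  set.seed(masterSeed)
  absDir <- runif(n, 5, 85)
  ecc <- runif(n, 2, 25)
  sign <- rep(c(1, -1), c(nUpper, nLower))
  dirs <- absDir * sign
  seeds <- sessionSeeds(masterSeed, n)
  if (!is.null(outPath) && !dir.exists(outPath))
    dir.create(outPath, recursive = TRUE)
  sessions <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    geom <- siteGeometry(ecc[i], dirs[i])
    sid <- sprintf("%s_%s_%03d", task, if (sign[i] > 0) "upper" else "lower", i)
    bundle <- simulateSession(task, geom, trialsPerSession, config,
                              seed = seeds[i], sessionId = sid,
                              spikes = spikes)
    path <- NA_character_; checksum <- NA_character_
    if (!is.null(outPath)) {
      path <- file.path(outPath, sid)
      entry <- writeBundle(bundle, path)
      checksum <- entry$checksum
    }
    rows[[i]] <- data.frame(session_id = sid, task = task,
                            field = if (sign[i] > 0) "upper" else "lower",
                            eccentricity_deg = ecc[i], direction_deg = dirs[i],
                            seed = seeds[i], path = path, checksum = checksum,
                            stringsAsFactors = FALSE)
    if (!is.null(processFUN)) sessions[[i]] <- processFUN(bundle)
    else if (keepInMemory) sessions[[i]] <- bundle
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outPath))
    utils::write.csv(manifest, file.path(outPath, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest,
       sessions = if (keepInMemory || !is.null(processFUN)) sessions else NULL)
}

## mains interference: sum of sinusoids at the line frequencies. When all
## line periods divide a common sample count L (the usual case for integer
## frequencies at integer fs), one L-sample template is tiled across the
## recording, which is exact and much cheaper than evaluating sin at every
## sample.
lineNoise <- function(n, fs, freqsHz, ampsUv, phases) {
  tmpl <- NULL
  if (abs(fs - round(fs)) < 1e-9 && all(abs(freqsHz - round(freqsHz)) < 1e-9)) {
    periods <- fs / vapply(freqsHz, function(f) gcd2(round(fs), round(f)),
                           numeric(1))
    L <- Reduce(lcm2, periods)
    if (is.finite(L) && L <= 1e6 && L < n) {
      k <- 0:(L - 1)
      tmpl <- numeric(L)
      for (j in seq_along(freqsHz))
        if (ampsUv[j] > 0)
          tmpl <- tmpl + ampsUv[j] * sin(2 * pi * freqsHz[j] * k / fs +
                                           phases[j])
      return(rep_len(tmpl, n))
    }
  }
  tS <- (0:(n - 1)) / fs
  x <- numeric(n)
  for (j in seq_along(freqsHz))
    if (ampsUv[j] > 0)
      x <- x + ampsUv[j] * sin(2 * pi * freqsHz[j] * tS + phases[j])
  x
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a / gcd2(a, b) * b

## optional acquisition-hardware band-pass emulation (0.7 Hz - 6 kHz)
applyHardwareBandpass <- function(rec) {
  fs <- samplingRate(rec)
  hp <- signal::butter(1, 0.7 / (fs / 2), type = "high")
  lp <- signal::butter(4, min(6000 / (fs / 2), 0.99), type = "low")
  x <- zeroPhaseFilter(hp$b, hp$a, samples(rec))
  x <- zeroPhaseFilter(lp$b, lp$a, x)
  widebandRecording(x, fs, startTime(rec))
}
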