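#' @import methods
#' @importFrom Rcpp sourceCpp evalCpp
#' @useDynLib periLFP, .registration = TRUE
NULL

#' Continuous neural signal traces
#'
#' `ContinuousTrace` is the virtual parent of all regularly sampled signals:
#' `WidebandRecording` (raw electrode voltage, typically 40 kHz),
#' `LfpTrace` (conditioned local field potential at 1 kHz) and
#' `RatePath` (instantaneous firing rate in spikes/s on a 1 kHz grid).
#' Samples are microvolts for voltage traces and spikes/s for rate paths;
#' `t0S` is the time of the first sample in seconds from recording start.
#'
#' @slot samples numeric vector of sample values.
#' @slot fsHz sampling rate in Hz.
#' @slot t0S time of the first sample, seconds.
#'
#' @aliases ContinuousTrace-class WidebandRecording-class LfpTrace-class
#'   RatePath-class
#' @name ContinuousTrace
#' @rdname ContinuousTrace
#' @exportClass WidebandRecording
#' @exportClass LfpTrace
#' @exportClass RatePath
setClass("ContinuousTrace",
  representation("VIRTUAL", samples = "numeric", fsHz = "numeric",
                 t0S = "numeric"),
  prototype(fsHz = 40000, t0S = 0),
  validity = function(object) {
    if (length(object@fsHz) != 1L || !is.finite(object@fsHz) ||
        object@fsHz <= 0)
      return("fsHz must be a single positive finite number")
    if (length(object@t0S) != 1L || !is.finite(object@t0S))
      return("t0S must be a single finite number")
    if (anyNA(object@samples) || any(!is.finite(object@samples)))
      return("all samples must be finite")
    TRUE
  })

setClass("WidebandRecording", contains = "ContinuousTrace")
setClass("LfpTrace", contains = "ContinuousTrace")
setClass("RatePath", contains = "ContinuousTrace",
  validity = function(object) {
    if (length(object@samples) && min(object@samples) < -1e-9)
      return("firing rates must be non-negative")
    TRUE
  })
setClassUnion("traceOrNULL", c("ContinuousTrace", "NULL"))

#' @rdname ContinuousTrace
#' @param samples numeric sample vector.
#' @param fsHz sampling rate in Hz.
#' @param t0S time of first sample in seconds.
#' @return A `WidebandRecording`, `LfpTrace` or `RatePath` object.
#' @examples
#' widebandRecording(rnorm(400), fsHz = 400)
#' @export
widebandRecording <- function(samples, fsHz = 40000, t0S = 0) {
  new("WidebandRecording", samples = as.numeric(samples),
      fsHz = as.numeric(fsHz), t0S = as.numeric(t0S))
}

#' @rdname ContinuousTrace
#' @export
lfpTrace <- function(samples, fsHz = 1000, t0S = 0) {
  new("LfpTrace", samples = as.numeric(samples), fsHz = as.numeric(fsHz),
      t0S = as.numeric(t0S))
}

#' @rdname ContinuousTrace
#' @export
ratePath <- function(samples, fsHz = 1000, t0S = 0) {
  new("RatePath", samples = as.numeric(samples), fsHz = as.numeric(fsHz),
      t0S = as.numeric(t0S))
}

#' Spike train
#'
#' Sorted, unique spike times in seconds from recording start, together with
#' the recording duration that bounds them.
#'
#' @slot times numeric, strictly increasing spike times in seconds.
#' @slot durationS recording duration in seconds.
#' @aliases SpikeTrain-class
#' @exportClass SpikeTrain
#' @name SpikeTrain
#' @rdname SpikeTrain
setClass("SpikeTrain",
  representation(times = "numeric", durationS = "numeric"),
  validity = function(object) {
    t <- object@times
    if (anyNA(t) || any(!is.finite(t))) return("spike times must be finite")
    if (is.unsorted(t, strictly = TRUE)) return("spike times must be strictly increasing")
    if (length(t) && (t[1] < 0 || t[length(t)] > object@durationS))
      return("spike times must lie within [0, durationS]")
    TRUE
  })

#' @rdname SpikeTrain
#' @param times numeric spike times, seconds.
#' @param durationS recording duration, seconds.
#' @return A `SpikeTrain`.
#' @examples
#' spikeTrain(c(0.1, 0.5, 0.9), durationS = 1)
#' @export
spikeTrain <- function(times, durationS) {
  new("SpikeTrain", times = as.numeric(times), durationS = as.numeric(durationS))
}

#' Retinotopic site geometry
#'
#' Location of a session's electrode track in visual-field coordinates:
#' eccentricity (degrees of visual angle, positive) and direction from the
#' horizontal meridian (degrees in \[-90, 90\], positive above the horizon).
#' Sites exactly on the horizon (direction 0) are rejected because they belong
#' to neither visual-field group.
#'
#' @slot eccentricityDeg eccentricity in degrees, > 0.
#' @slot directionDeg direction from horizontal in degrees, non-zero.
#' @aliases SiteGeometry-class
#' @exportClass SiteGeometry
#' @name SiteGeometry
#' @rdname SiteGeometry
setClass("SiteGeometry",
  representation(eccentricityDeg = "numeric", directionDeg = "numeric"),
  validity = function(object) {
    e <- object@eccentricityDeg; d <- object@directionDeg
    if (length(e) != 1L || !is.finite(e) || e <= 0)
      return("eccentricityDeg must be a single positive number")
    if (length(d) != 1L || !is.finite(d) || d < -90 || d > 90)
      return("directionDeg must lie in [-90, 90]")
    if (d == 0)
      return("directionDeg must be non-zero (horizon sites are excluded)")
    TRUE
  })

#' @rdname SiteGeometry
#' @param eccentricityDeg eccentricity in degrees of visual angle, > 0.
#' @param directionDeg direction from horizontal meridian in degrees;
#'   positive = upper visual field; must be non-zero.
#' @return A `SiteGeometry`.
#' @examples
#' siteGeometry(5, 10)   # 5 deg eccentric, upper visual field
#' @export
siteGeometry <- function(eccentricityDeg, directionDeg) {
  new("SiteGeometry", eccentricityDeg = as.numeric(eccentricityDeg),
      directionDeg = as.numeric(directionDeg))
}

#' Event-aligned epoch matrix
#'
#' Trials-by-time array of a signal aligned to a named trial event, on a 1 ms
#' grid over a half-open peri-event window \[a, b) ms. Row `i` holds trial
#' `i`'s samples at lags `a, a+1, ..., b-1` ms from the event.
#'
#' @slot values numeric matrix, trials x time.
#' @slot alignEvent character, the aligning event column name.
#' @slot windowMs numeric length-2, the half-open window in ms.
#' @slot timeAxisMs numeric, lag of each column in ms.
#' @slot unit character, "uV" or "sp/s".
#' @aliases EpochMatrix-class
#' @exportClass EpochMatrix
#' @name EpochMatrix
#' @rdname EpochMatrix
setClass("EpochMatrix",
  representation(values = "matrix", alignEvent = "character",
                 windowMs = "numeric", timeAxisMs = "numeric",
                 unit = "character"),
  validity = function(object) {
    if (ncol(object@values) != length(object@timeAxisMs))
      return("time axis length must equal number of columns")
    if (length(object@windowMs) != 2L || object@windowMs[2] <= object@windowMs[1])
      return("windowMs must be an increasing pair")
    if (length(object@timeAxisMs) &&
        object@timeAxisMs[1] != object@windowMs[1])
      return("time axis must start at the window start")
    TRUE
  })

#' Group average with SEM
#'
#' Pointwise mean and standard error across session-mean time series, as used
#' to draw grand-average peri-event curves with SEM bounds.
#'
#' @slot mean numeric, pointwise mean across sessions.
#' @slot sem numeric, pointwise SEM (sample SD / sqrt(n)).
#' @slot n integer, number of sessions.
#' @slot timeAxisMs numeric, lag axis in ms.
#' @aliases GroupAverage-class
#' @exportClass GroupAverage
#' @name GroupAverage
#' @rdname GroupAverage
setClass("GroupAverage",
  representation(mean = "numeric", sem = "numeric", n = "integer",
                 timeAxisMs = "numeric"),
  validity = function(object) {
    if (length(object@mean) != length(object@sem))
      return("mean and sem must have equal length")
    if (length(object@sem) && min(object@sem) < 0)
      return("sem must be non-negative")
    TRUE
  })

#' Session bundle
#'
#' One recording session: metadata, per-trial event table, spike train and the
#' continuous signals (raw wideband voltage, preprocessed LFP, spike-density
#' rate path; each optional).
#'
#' @slot sessionId character session identifier.
#' @slot task character, "visual" or "memory".
#' @slot geometry the site's [SiteGeometry].
#' @slot events data.frame of per-trial event times (seconds).
#' @slot spikes a [SpikeTrain].
#' @slot raw optional `WidebandRecording`.
#' @slot lfp optional `LfpTrace`.
#' @slot rate optional `RatePath`.
#' @slot seed integer generator seed (NA for imported data).
#' @slot metadata list of additional metadata (preprocessing block etc.).
#' @aliases SessionBundle-class
#' @exportClass SessionBundle
#' @name SessionBundle
#' @rdname SessionBundle
setClass("SessionBundle",
  representation(sessionId = "character", task = "character",
                 geometry = "SiteGeometry", events = "data.frame",
                 spikes = "SpikeTrain", raw = "traceOrNULL",
                 lfp = "traceOrNULL", rate = "traceOrNULL",
                 seed = "numeric", metadata = "list"),
  prototype(raw = NULL, lfp = NULL, rate = NULL, seed = NA_real_,
            metadata = list()),
  validity = function(object) {
    if (!(object@task %in% c("visual", "memory")))
      return("task must be 'visual' or 'memory'")
    req <- c("trial_id", "fixation_on_s", "target_on_s", "target_off_s",
             "go_s", "saccade_on_s", "saccade_off_s")
    if (!all(req %in% names(object@events)))
      return(paste("events table must have columns:", paste(req, collapse = ", ")))
    ev <- object@events
    ok <- ev$fixation_on_s < ev$target_on_s & ev$target_on_s < ev$go_s &
      ev$go_s < ev$saccade_on_s & ev$saccade_on_s < ev$saccade_off_s
    if (nrow(ev) && !all(ok))
      return(sprintf("event ordering violated in trial(s) %s",
                     paste(ev$trial_id[!ok], collapse = ", ")))
    TRUE
  })

#' Statistical test result
#'
#' Holds the test statistic, degrees of freedom, two-sided (t) or upper-tail
#' (F) p-value and group sizes of one group-level test.
#'
#' @slot statistic numeric test statistic (t or F).
#' @slot df numeric, one (t) or two (F) degrees of freedom.
#' @slot pValue numeric p-value in \[0, 1\].
#' @slot testName character test label.
#' @slot nPerGroup integer group sizes.
#' @aliases StatResult-class
#' @exportClass StatResult
#' @name StatResult
#' @rdname StatResult
setClass("StatResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 testName = "character", nPerGroup = "integer"),
  validity = function(object) {
    if (!is.finite(object@pValue) || object@pValue < 0 || object@pValue > 1)
      return("pValue must lie in [0, 1]")
    if (any(object@df <= 0)) return("degrees of freedom must be positive")
    TRUE
  })
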