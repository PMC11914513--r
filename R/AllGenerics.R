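#' Accessors for periLFP data classes
#'
#' Small accessor generics used instead of direct slot access: `samples()`,
#' `samplingRate()` and `startTime()` for continuous traces; `spikeTimes()`
#' and `recordingDuration()` for spike trains; `eccentricity()` and
#' `direction()` for site geometries; `epochValues()`, `timeAxis()`,
#' `alignEvent()` and `nTrials()` for epoch matrices; `statistic()`,
#' `degreesOfFreedom()` and `pValue()` for test results; `sessionEvents()`,
#' `sessionTask()` and `sessionGeometry()` for session bundles.
#'
#' @param x object to access.
#' @return The corresponding slot value.
#' @examples
#' tr <- lfpTrace(rnorm(100))
#' samplingRate(tr)
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("eccentricity", function(x) standardGeneric("eccentricity"))
#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname accessors
#' @export
setGeneric("epochValues", function(x) standardGeneric("epochValues"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("alignEvent", function(x) standardGeneric("alignEvent"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setGeneric("degreesOfFreedom", function(x) standardGeneric("degreesOfFreedom"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("sessionEvents", function(x) standardGeneric("sessionEvents"))
#' @rdname accessors
#' @export
setGeneric("sessionTask", function(x) standardGeneric("sessionTask"))
#' @rdname accessors
#' @export
setGeneric("sessionGeometry", function(x) standardGeneric("sessionGeometry"))

setMethod("samples", "ContinuousTrace", function(x) x@samples)
setMethod("samplingRate", "ContinuousTrace", function(x) x@fsHz)
setMethod("startTime", "ContinuousTrace", function(x) x@t0S)
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
setMethod("recordingDuration", "SpikeTrain", function(x) x@durationS)
setMethod("eccentricity", "SiteGeometry", function(x) x@eccentricityDeg)
setMethod("direction", "SiteGeometry", function(x) x@directionDeg)
setMethod("epochValues", "EpochMatrix", function(x) x@values)
setMethod("timeAxis", "EpochMatrix", function(x) x@timeAxisMs)
setMethod("timeAxis", "GroupAverage", function(x) x@timeAxisMs)
setMethod("alignEvent", "EpochMatrix", function(x) x@alignEvent)
setMethod("nTrials", "EpochMatrix", function(x) nrow(x@values))
setMethod("statistic", "StatResult", function(x) x@statistic)
setMethod("degreesOfFreedom", "StatResult", function(x) x@df)
setMethod("pValue", "StatResult", function(x) x@pValue)
setMethod("sessionEvents", "SessionBundle", function(x) x@events)
setMethod("sessionTask", "SessionBundle", function(x) x@task)
setMethod("sessionGeometry", "SessionBundle", function(x) x@geometry)

setMethod("show", "ContinuousTrace", function(object) {
  cat(sprintf("%s: %d samples at %g Hz (%.3f s), t0 = %.3f s\n",
              class(object), length(object@samples), object@fsHz,
              length(object@samples) / object@fsHz, object@t0S))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes over %.3f s (mean rate %.2f sp/s)\n",
              length(object@times), object@durationS,
              length(object@times) / max(object@durationS, .Machine$double.eps)))
})

setMethod("show", "SiteGeometry", function(object) {
  cat(sprintf("SiteGeometry: eccentricity %.1f deg, direction %+.1f deg (%s visual field)\n",
              object@eccentricityDeg, object@directionDeg,
              if (object@directionDeg > 0) "upper" else "lower"))
})

setMethod("show", "EpochMatrix", function(object) {
  cat(sprintf("EpochMatrix: %d trials x %d ms, aligned to %s, window [%g, %g) ms [%s]\n",
              nrow(object@values), ncol(object@values), object@alignEvent,
              object@windowMs[1], object@windowMs[2], object@unit))
})

setMethod("show", "GroupAverage", function(object) {
  cat(sprintf("GroupAverage over %d sessions, %d time points ([%g, %g] ms)\n",
              object@n, length(object@mean),
              if (length(object@timeAxisMs)) object@timeAxisMs[1] else NA,
              if (length(object@timeAxisMs)) object@timeAxisMs[length(object@timeAxisMs)] else NA))
})

setMethod("show", "SessionBundle", function(object) {
  cat(sprintf("SessionBundle '%s' (%s task): %d trials, %d spikes\n",
              object@sessionId, object@task, nrow(object@events),
              length(object@spikes@times)))
  show(object@geometry)
  has <- c(raw = !is.null(object@raw), lfp = !is.null(object@lfp),
           rate = !is.null(object@rate))
  cat("  signals:", if (any(has)) paste(names(has)[has], collapse = ", ")
      else "none", "\n")
})

setMethod("show", "StatResult", function(object) {
  dfs <- paste(format(object@df, trim = TRUE), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = (%s), p = %.4g\n",
              object@testName, object@statistic, dfs, object@pValue))
})
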