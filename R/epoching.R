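## event time -> sample index on the trace grid, round-half-up to the
## nearest sample (ties at .5 go up); small epsilon guards float wobble
eventSampleIndex <- function(eventTimeS, trace) {
  as.integer(floor((eventTimeS - startTime(trace)) * samplingRate(trace) +
                     0.5 + 1e-9))
}

#' Extract one event-aligned epoch
#'
#' Returns the trace samples in the half-open window \[a, b) ms around an
#' event: samples at lags a, a+1, ..., b-1 ms. The event time is rounded
#' half-up to the nearest sample of the 1 kHz grid.
#'
#' @param trace an [lfpTrace()] or [ratePath()] at 1 kHz.
#' @param eventTimeS event time in seconds from recording start.
#' @param windowMs length-2 numeric, the half-open window in ms.
#' @param trialId optional trial label used in error messages.
#' @return Numeric vector of length `windowMs[2] - windowMs[1]`.
#' @examples
#' tr <- lfpTrace(rep(5, 2000))
#' length(extractEpoch(tr, 1.0, c(-200, 200)))   # 400
#' @export
extractEpoch <- function(trace, eventTimeS, windowMs, trialId = NULL) {
  stopifnot(is(trace, "ContinuousTrace"), length(windowMs) == 2L,
            windowMs[2] > windowMs[1])
  fs <- samplingRate(trace)
  if (abs(fs - 1000) > 1e-9)
    stop("epoching expects a 1 kHz trace (run the conditioning chain first)")
  k0 <- eventSampleIndex(eventTimeS, trace)
  idx <- k0 + seq.int(windowMs[1], windowMs[2] - 1)
  if (idx[1] < 0 || idx[length(idx)] >= length(samples(trace)))
    stop(sprintf("epoch window [%g, %g) ms exceeds recording bounds%s",
                 windowMs[1], windowMs[2],
                 if (is.null(trialId)) "" else sprintf(" in trial %s", trialId)))
  samples(trace)[idx + 1L]
}

#' Build an event-aligned epoch matrix for a session
#'
#' Extracts one epoch per trial of the chosen signal, aligned to a named
#' trial event, into a trials-by-time [EpochMatrix]. Trials whose window
#' exceeds the recording bounds are dropped with a message reporting the
#' count; an error is raised if no trial survives.
#'
#' @param bundle a [SessionBundle] (needs `lfp` for `signal = "lfp"`, or a
#'   raw recording already at 1 kHz; `rate` for `signal = "rate"`).
#' @param signal "lfp" (microvolts) or "rate" (spikes/s).
#' @param alignEvent one of "target_on", "go", "saccade_on" (any event
#'   column of the trial table, without the `_s` suffix).
#' @param windowMs half-open peri-event window in ms.
#' @return An [EpochMatrix].
#' @export
buildEpochMatrix <- function(bundle, signal = c("lfp", "rate"),
                             alignEvent = "saccade_on",
                             windowMs = c(-200, 200)) {
  signal <- match.arg(signal)
  stopifnot(is(bundle, "SessionBundle"))
  trace <- if (signal == "lfp") {
    if (!is.null(bundle@lfp)) bundle@lfp
    else if (!is.null(bundle@raw) &&
             abs(samplingRate(bundle@raw) - 1000) < 1e-9) bundle@raw
    else stop("bundle has no 1 kHz LFP signal; run preprocessSession() first")
  } else {
    if (is.null(bundle@rate))
      stop("bundle has no rate signal; run preprocessSession() first")
    bundle@rate
  }
  col <- paste0(alignEvent, "_s")
  ev <- sessionEvents(bundle)
  if (!col %in% names(ev))
    stop(sprintf("unknown align event '%s'", alignEvent))
  times <- ev[[col]]
  rows <- vector("list", length(times))
  kept <- logical(length(times))
  for (i in seq_along(times)) {
    rows[i] <- list(tryCatch(
      extractEpoch(trace, times[i], windowMs, trialId = ev$trial_id[i]),
      error = function(e) NULL))
    kept[i] <- !is.null(rows[[i]])
  }
  if (!all(kept))
    message(sprintf("dropped %d/%d trial(s) with out-of-bounds windows",
                    sum(!kept), length(kept)))
  if (!any(kept)) stop("no trial left after window-bound screening")
  values <- do.call(rbind, rows[kept])
  rownames(values) <- ev$trial_id[kept]
  new("EpochMatrix", values = values, alignEvent = alignEvent,
      windowMs = as.numeric(windowMs),
      timeAxisMs = seq.int(windowMs[1], windowMs[2] - 1),
      unit = if (signal == "lfp") "uV" else "sp/s")
}

#' Within-session trial average
#'
#' Pointwise arithmetic mean across the trials of an epoch matrix: the
#' session's mean peri-event curve.
#'
#' @param epochs an [EpochMatrix] with at least one row.
#' @return Numeric time series with a `timeAxisMs` attribute.
#' @export
sessionMean <- function(epochs) {
  stopifnot(is(epochs, "EpochMatrix"), nrow(epochValues(epochs)) >= 1)
  m <- colMeans(epochValues(epochs))
  attr(m, "timeAxisMs") <- timeAxis(epochs)
  m
}

#' Across-session group average with SEM
#'
#' Pointwise mean and SEM (sample SD with n-1 denominator, divided by
#' sqrt(n)) across session-mean curves. Operates on session means regardless
#' of each session's trial count, i.e. every session weighs equally.
#'
#' @param sessionMeans list of equal-length numeric series (from
#'   [sessionMean()]).
#' @return A [GroupAverage].
#' @examples
#' ga <- groupAverage(list(c(0, 0), c(2, 2)))
#' ga@mean   # 1 1
#' ga@sem    # 1 1
#' @export
groupAverage <- function(sessionMeans) {
  stopifnot(is.list(sessionMeans), length(sessionMeans) >= 2)
  len <- lengths(sessionMeans)
  if (length(unique(len)) != 1L)
    stop("session means differ in length")
  m <- do.call(rbind, lapply(sessionMeans, as.numeric))
  n <- nrow(m)
  mu <- colMeans(m)
  sem <- apply(m, 2, stats::sd) / sqrt(n)
  axis <- attr(sessionMeans[[1]], "timeAxisMs")
  new("GroupAverage", mean = mu, sem = sem, n = as.integer(n),
      timeAxisMs = if (is.null(axis)) numeric(0) else as.numeric(axis))
}

#' Export an epoch matrix or group average as CSV
#'
#' Epoch matrices are written one row per trial with the lag (ms) as header;
#' group averages as columns `lag_ms`, `mean`, `sem`, `n`.
#'
#' @param x an [EpochMatrix] or [GroupAverage].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportCsv <- function(x, path) {
  if (is(x, "EpochMatrix")) {
    df <- as.data.frame(epochValues(x))
    names(df) <- timeAxis(x)
    ids <- rownames(epochValues(x))
    if (is.null(ids)) ids <- seq_len(nrow(df))
    utils::write.csv(cbind(trial_id = ids, df), path, row.names = FALSE)
  } else if (is(x, "GroupAverage")) {
    lag <- if (length(x@timeAxisMs)) x@timeAxisMs else seq_along(x@mean) - 1
    utils::write.csv(data.frame(lag_ms = lag, mean = x@mean,
                                sem = x@sem, n = x@n), path,
                     row.names = FALSE)
  } else stop("exportCsv handles EpochMatrix or GroupAverage objects")
  invisible(path)
}
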