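#' Standard measurement windows
#'
#' The named scalar-measurement windows of the analysis, each a half-open
#' interval \[a, b) ms relative to an aligning event with a summary mode:
#' \describe{
#'   \item{PERISACC}{0 to 50 ms after saccade onset, mean — the peri-saccadic
#'     LFP/rate measurement.}
#'   \item{PRESACC}{-50 to 0 ms before saccade onset, mean.}
#'   \item{GO}{-50 to +25 ms around the go signal, mean — the delay-period
#'     level at the end of the delay.}
#'   \item{STIMPEAK}{30 to 100 ms after target onset, most negative sample —
#'     the stimulus-evoked peak negativity.}
#'   \item{BASELINE}{-300 to -200 ms before saccade onset, mean — the
#'     pre-saccadic baseline used by [baselineShift()].}
#' }
#'
#' @param name one of "PERISACC", "PRESACC", "GO", "STIMPEAK", "BASELINE".
#' @return A list with `name`, `alignEvent`, `intervalMs` and `mode`.
#' @examples
#' measurementWindow("PERISACC")
#' @export
measurementWindow <- function(name = c("PERISACC", "PRESACC", "GO",
                                       "STIMPEAK", "BASELINE")) {
  name <- match.arg(name)
  switch(name,
    PERISACC = list(name = name, alignEvent = "saccade_on",
                    intervalMs = c(0, 50), mode = "mean"),
    PRESACC = list(name = name, alignEvent = "saccade_on",
                   intervalMs = c(-50, 0), mode = "mean"),
    GO = list(name = name, alignEvent = "go",
              intervalMs = c(-50, 25), mode = "mean"),
    STIMPEAK = list(name = name, alignEvent = "target_on",
                    intervalMs = c(30, 100), mode = "most_negative"),
    BASELINE = list(name = name, alignEvent = "saccade_on",
                    intervalMs = c(-300, -200), mode = "mean"))
}

seriesAxis <- function(series, timeAxisMs) {
  if (is.null(timeAxisMs)) timeAxisMs <- attr(series, "timeAxisMs")
  if (is.null(timeAxisMs))
    stop("no time axis: pass timeAxisMs or a series from sessionMean()")
  if (length(timeAxisMs) != length(series))
    stop("time axis and series lengths differ")
  timeAxisMs
}

#' Windowed scalar measurement
#'
#' Reduces a peri-event time series to one scalar over a half-open interval:
#' the arithmetic mean (`mode = "mean"`) or the minimum value
#' (`mode = "most_negative"`, for peak negativities).
#'
#' @param series numeric peri-event series (e.g. from [sessionMean()]).
#' @param window a [measurementWindow()] or a list with `intervalMs` and
#'   `mode`.
#' @param timeAxisMs lag axis in ms; taken from the series attribute when
#'   omitted.
#' @return A single numeric value.
#' @examples
#' s <- 1:5
#' windowMeasure(s, list(intervalMs = c(0, 5), mode = "mean"),
#'               timeAxisMs = 0:4)   # 3
#' @export
windowMeasure <- function(series, window, timeAxisMs = NULL) {
  timeAxisMs <- seriesAxis(series, timeAxisMs)
  sel <- timeAxisMs >= window$intervalMs[1] & timeAxisMs < window$intervalMs[2]
  if (!any(sel)) stop("measurement window lies outside the series")
  v <- as.numeric(series)[sel]
  switch(window$mode,
         mean = mean(v),
         most_negative = min(v),
         stop(sprintf("unknown window mode '%s'", window$mode)))
}

#' Baseline shift
#'
#' Subtracts the mean of a pre-event baseline interval from the whole series,
#' so the shifted series averages exactly zero over the baseline window.
#' Idempotent. Used to remove sustained pre-saccadic (e.g. working-memory)
#' LFP levels before measuring peri-saccadic deflections.
#'
#' @param series numeric peri-event series.
#' @param baselineMs half-open baseline interval in ms (default -300 to -200
#'   relative to the aligning event).
#' @param timeAxisMs lag axis in ms; taken from the series attribute when
#'   omitted.
#' @return The shifted series (attributes preserved).
#' @export
baselineShift <- function(series, baselineMs = c(-300, -200),
                          timeAxisMs = NULL) {
  timeAxisMs <- seriesAxis(series, timeAxisMs)
  sel <- timeAxisMs >= baselineMs[1] & timeAxisMs < baselineMs[2]
  if (!any(sel)) stop("baseline interval not covered by the series")
  out <- series - mean(as.numeric(series)[sel])
  out
}

#' Visual-field classification of a site
#'
#' Upper visual field iff the direction from the horizontal meridian is
#' positive. Horizon sites (direction 0) are rejected by [siteGeometry()].
#'
#' @param geometry a [siteGeometry()].
#' @return "upper" or "lower".
#' @examples
#' classifyField(siteGeometry(5, 10))    # "upper"
#' classifyField(siteGeometry(5, -10))   # "lower"
#' @export
classifyField <- function(geometry) {
  validObject(geometry)
  if (direction(geometry) > 0) "upper" else "lower"
}

#' Per-session windowed measurements of a dataset
#'
#' For each session: build the epoch matrix of the chosen signal around the
#' window's aligning event, average across trials, optionally baseline-shift,
#' and reduce to one scalar with [windowMeasure()]. Returns the session
#' measurement table that feeds binning and statistics.
#'
#' @param sessions list of [SessionBundle] objects.
#' @param signal "lfp" or "rate".
#' @param windowName a [measurementWindow()] name.
#' @param baseline if TRUE, apply [baselineShift()] (baseline -300 to -200 ms
#'   before saccade onset) to each session mean first. Only meaningful for
#'   saccade-aligned windows.
#' @param epochMs epoch span used for extraction; must cover the measurement
#'   window (and the baseline when `baseline = TRUE`).
#' @return data.frame with columns `session_id`, `signal`, `window`, `field`,
#'   `eccentricity_deg`, `direction_deg`, `value`.
#' @export
sessionMeasurements <- function(sessions, signal = c("lfp", "rate"),
                                windowName = "PERISACC", baseline = FALSE,
                                epochMs = c(-300, 200)) {
  signal <- match.arg(signal)
  win <- measurementWindow(windowName)
  rows <- lapply(sessions, function(b) {
    em <- buildEpochMatrix(b, signal, win$alignEvent, epochMs)
    m <- sessionMean(em)
    if (baseline) m <- baselineShift(m)
    g <- sessionGeometry(b)
    data.frame(session_id = b@sessionId, signal = signal,
               window = win$name, field = classifyField(g),
               eccentricity_deg = eccentricity(g),
               direction_deg = direction(g),
               value = windowMeasure(m, win), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Direction-bin memberships
#'
#' Candidate direction bins are half-open intervals of |direction| with lower
#' edges 0, `stepDeg`, 2*`stepDeg`, ... and width `widthDeg`, built per
#' visual field so that no bin straddles the horizontal meridian. With the
#' default 20-deg bins in 10-deg steps the bins overlap, so a session can be
#' a member of up to two bins (a site at |direction| not on a bin edge joins
#' exactly two candidate bins; membership counts then exceed the session
#' count, as in n = 351 memberships from 198 sessions).
#'
#' @param measurements a [sessionMeasurements()] table.
#' @param widthDeg bin width, degrees.
#' @param stepDeg step between bin lower edges, degrees.
#' @return data.frame of memberships: one row per (session, bin) pair with
#'   `bin_label`, `field`, `lo_deg`, `hi_deg` and the measurement columns.
#' @export
directionBinMembership <- function(measurements, widthDeg = 20, stepDeg = 10) {
  stopifnot(widthDeg > 0, stepDeg > 0, nrow(measurements) >= 1)
  lowerEdges <- seq(0, 90 - widthDeg, by = stepDeg)   # bins stay inside [0, 90]
  out <- list()
  for (lo in lowerEdges) {
    hi <- lo + widthDeg
    member <- abs(measurements$direction_deg) >= lo &
      abs(measurements$direction_deg) < lo + widthDeg
    if (!any(member)) next
    sub <- measurements[member, , drop = FALSE]
    sub$lo_deg <- lo
    sub$hi_deg <- hi
    sub$bin_label <- sprintf("%s[%g,%g)", ifelse(sub$field == "upper", "U", "L"),
                             lo, hi)
    out[[length(out) + 1L]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Direction-bin summaries
#'
#' Bins session measurements by |direction from horizontal| per visual field
#' (overlapping sliding bins, see [directionBinMembership()]), drops bins
#' with fewer than `minN` members, and summarizes each retained bin with its
#' member count, mean and SEM.
#'
#' @inheritParams directionBinMembership
#' @param minN minimum memberships for a bin to be retained.
#' @return data.frame with `bin_label`, `field`, `lo_deg`, `hi_deg`, `n`,
#'   `mean`, `sem`, ordered by field (upper first) and descending |direction|
#'   for upper / ascending for lower. May have zero rows.
#' @examples
#' m <- data.frame(session_id = 1:12, field = "upper",
#'                 direction_deg = rep(15, 12), eccentricity_deg = 5,
#'                 value = rnorm(12))
#' directionBins(m)   # one session set, two overlapping bins
#' @export
directionBins <- function(measurements, widthDeg = 20, stepDeg = 10,
                          minN = 10) {
  mem <- directionBinMembership(measurements, widthDeg, stepDeg)
  if (is.null(mem) || nrow(mem) == 0)
    return(emptyBinTable())
  sp <- split(mem, list(mem$field, mem$bin_label), drop = TRUE)
  rows <- lapply(sp, function(g) {
    data.frame(bin_label = g$bin_label[1], field = g$field[1],
               lo_deg = g$lo_deg[1], hi_deg = g$hi_deg[1], n = nrow(g),
               mean = mean(g$value),
               sem = if (nrow(g) > 1) stats::sd(g$value) / sqrt(nrow(g)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$n >= minN, , drop = FALSE]
  if (nrow(res) == 0) return(emptyBinTable())
  ord <- order(res$field == "lower",
               ifelse(res$field == "upper", -res$lo_deg, res$lo_deg))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

emptyBinTable <- function() {
  data.frame(bin_label = character(0), field = character(0),
             lo_deg = numeric(0), hi_deg = numeric(0), n = integer(0),
             mean = numeric(0), sem = numeric(0), stringsAsFactors = FALSE)
}

#' Measurement groups per retained direction bin
#'
#' Returns the per-bin lists of member values (both fields), for the one-way
#' ANOVA across angular direction bins. Because bins overlap, a session
#' contributes to every bin containing it and the total count exceeds the
#' number of sessions.
#'
#' @inheritParams directionBins
#' @return Named list of numeric vectors, one per retained bin.
#' @export
directionBinGroups <- function(measurements, widthDeg = 20, stepDeg = 10,
                               minN = 10) {
  mem <- directionBinMembership(measurements, widthDeg, stepDeg)
  if (is.null(mem) || nrow(mem) == 0) return(list())
  key <- paste(mem$field, mem$bin_label)
  sp <- split(mem$value, key)
  sp[lengths(sp) >= minN]
}

#' Eccentricity-bin summaries
#'
#' Non-overlapping half-open eccentricity bins \[e_i, e_{i+1}) from the given
#' edges (default 0, 2, 5, 10, 30 deg — four bins). Summaries are computed
#' per field and bin; field-by-bin cells with no session are reported with
#' `n = 0` and NA mean (and are excluded from downstream statistics).
#' Sessions outside the outermost edges join no bin and are counted in a
#' message.
#'
#' @param measurements a [sessionMeasurements()] table.
#' @param edgesDeg increasing eccentricity bin edges, degrees.
#' @return data.frame with `bin_label`, `lo_deg`, `hi_deg`, `field`, `n`,
#'   `mean`, `sem`.
#' @export
eccentricityBins <- function(measurements, edgesDeg = c(0, 2, 5, 10, 30)) {
  stopifnot(length(edgesDeg) >= 2, all(diff(edgesDeg) > 0))
  e <- measurements$eccentricity_deg
  out <- e < edgesDeg[1] | e >= edgesDeg[length(edgesDeg)]
  if (any(out))
    message(sprintf("%d session(s) outside the eccentricity edges were not binned",
                    sum(out)))
  m <- measurements[!out, , drop = FALSE]
  binIdx <- findInterval(m$eccentricity_deg, edgesDeg)
  rows <- list()
  for (b in seq_len(length(edgesDeg) - 1)) {
    for (f in c("upper", "lower")) {
      sel <- binIdx == b & m$field == f
      v <- m$value[sel]
      rows[[length(rows) + 1L]] <- data.frame(
        bin_label = sprintf("[%g,%g)", edgesDeg[b], edgesDeg[b + 1]),
        lo_deg = edgesDeg[b], hi_deg = edgesDeg[b + 1], field = f,
        n = length(v), mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Upper/lower visual-field asymmetry ratio
#'
#' Ratio of the absolute group means: |mean(upper values)| / |mean(lower
#' values)|. Computed from group means (not the mean of per-session ratios),
#' matching how the grand-average asymmetry is quoted.
#'
#' @param upperValues,lowerValues numeric session measurements per field.
#' @return A single positive number.
#' @examples
#' asymmetryRatio(c(-2.7, -2.7), c(-1, -1))   # 2.7
#' @export
asymmetryRatio <- function(upperValues, lowerValues) {
  stopifnot(length(upperValues) >= 1, length(lowerValues) >= 1)
  ml <- mean(lowerValues)
  if (abs(ml) < .Machine$double.eps)
    stop("lower-field mean is zero; asymmetry ratio undefined")
  abs(mean(upperValues)) / abs(ml)
}
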