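## required metadata keys of a session bundle
bundleMetaKeys <- c("session_id", "task", "geometry", "fs_hz", "seed",
                    "duration_s", "generator_version")

writeF32 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  invisible(path)
}

readF32 <- function(path, expectedN = NULL) {
  nBytes <- file.size(path)
  if (is.na(nBytes)) stop(sprintf("missing binary file '%s'", basename(path)))
  n <- nBytes / 4
  if (n != round(n))
    stop(sprintf("file '%s' is not a whole number of float32 samples",
                 basename(path)))
  if (!is.null(expectedN) && n != expectedN)
    stop(sprintf("length mismatch in '%s': %d samples on disk, %d expected",
                 basename(path), as.integer(n), as.integer(expectedN)))
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 4L, endian = "little")
}

## assign each spike to the trial whose span contains it (0 = inter-trial)
spikeTrialIds <- function(times, events) {
  if (!length(times)) return(integer(0))
  starts <- events$fixation_on_s
  ends <- c(events$fixation_on_s[-1], Inf)
  id <- findInterval(times, starts)
  id[id > 0 & times >= ends[pmax(id, 1)]] <- 0L
  as.integer(id)
}

#' Write a session bundle to disk
#'
#' Lays a session out as a plain directory: `metadata.json`, `events.csv`,
#' `spikes.csv` (`trial_id`, `spike_time_s`), and little-endian float32
#' arrays `lfp_raw.f32` (wideband), `lfp.f32` (1 kHz LFP) and `rate.f32`
#' (1 kHz spike density) for whichever signals are present. Refuses to write
#' a bundle whose invariants (event ordering, spike bounds) do not hold.
#'
#' @param bundle a [SessionBundle].
#' @param path target directory (created if needed).
#' @return A manifest entry: list with `path`, `files` and `checksum` (MD5
#'   over the per-file MD5s).
#' @export
writeBundle <- function(bundle, path) {
  validObject(bundle)
  validObject(bundle@spikes)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  durationS <- bundle@metadata$durationS
  if (is.null(durationS)) durationS <- recordingDuration(bundle@spikes)
  meta <- list(session_id = bundle@sessionId, task = bundle@task,
               geometry = list(eccentricity_deg = eccentricity(bundle@geometry),
                               direction_deg = direction(bundle@geometry)),
               fs_hz = if (!is.null(bundle@raw)) samplingRate(bundle@raw)
               else bundle@metadata$fsHz,
               seed = bundle@seed, duration_s = durationS,
               generator_version = as.character(utils::packageVersion("periLFP")))
  if (!is.null(bundle@raw)) meta$n_samples_raw <- length(samples(bundle@raw))
  if (!is.null(bundle@lfp)) {
    meta$n_samples_lfp <- length(samples(bundle@lfp))
    meta$fs_lfp_hz <- samplingRate(bundle@lfp)
  }
  if (!is.null(bundle@rate)) meta$n_samples_rate <- length(samples(bundle@rate))
  extra <- bundle@metadata[setdiff(names(bundle@metadata),
                                   c("fsHz", "durationS", "generator"))]
  meta <- c(meta, extra)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle@events, file.path(path, "events.csv"),
                   row.names = FALSE)
  spikesDf <- data.frame(
    trial_id = spikeTrialIds(spikeTimes(bundle@spikes), bundle@events),
    spike_time_s = spikeTimes(bundle@spikes))
  utils::write.csv(spikesDf, file.path(path, "spikes.csv"), row.names = FALSE)
  files <- c("metadata.json", "events.csv", "spikes.csv")
  if (!is.null(bundle@raw)) {
    writeF32(samples(bundle@raw), file.path(path, "lfp_raw.f32"))
    files <- c(files, "lfp_raw.f32")
  }
  if (!is.null(bundle@lfp)) {
    writeF32(samples(bundle@lfp), file.path(path, "lfp.f32"))
    files <- c(files, "lfp.f32")
  }
  if (!is.null(bundle@rate)) {
    writeF32(samples(bundle@rate), file.path(path, "rate.f32"))
    files <- c(files, "rate.f32")
  }
  sums <- tools::md5sum(file.path(path, files))
  tmp <- tempfile()
  writeLines(paste(files, unname(sums)), tmp)
  checksum <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(path = path, files = files, checksum = checksum)
}

#' Read a session bundle from disk
#'
#' Parses and validates a plain-directory bundle written by [writeBundle()].
#' Missing optional arrays (raw, preprocessed LFP, rate) are tolerated and
#' reported with a message; unknown extra metadata keys are preserved in the
#' bundle metadata with a warning; array-length mismatches against the
#' metadata are errors naming the file.
#'
#' @param path bundle directory containing `metadata.json`.
#' @return A [SessionBundle].
#' @export
readBundle <- function(path) {
  metaPath <- file.path(path, "metadata.json")
  if (!file.exists(metaPath))
    stop(sprintf("'%s' is not a session bundle (no metadata.json)", path))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  missing <- setdiff(bundleMetaKeys, names(meta))
  if (length(missing))
    stop(sprintf("metadata.json misses required key(s): %s",
                 paste(missing, collapse = ", ")))
  known <- c(bundleMetaKeys, "n_samples_raw", "n_samples_lfp", "fs_lfp_hz",
             "n_samples_rate", "preprocessing")
  extra <- setdiff(names(meta), known)
  if (length(extra))
    warning(sprintf("unknown metadata key(s) preserved: %s",
                    paste(extra, collapse = ", ")))
  events <- utils::read.csv(file.path(path, "events.csv"))
  spikesDf <- utils::read.csv(file.path(path, "spikes.csv"))
  geometry <- siteGeometry(meta$geometry$eccentricity_deg,
                           meta$geometry$direction_deg)
  raw <- NULL; lfp <- NULL; rate <- NULL
  if (file.exists(file.path(path, "lfp_raw.f32"))) {
    raw <- widebandRecording(readF32(file.path(path, "lfp_raw.f32"),
                                     meta$n_samples_raw),
                             fsHz = meta$fs_hz, t0S = 0)
  } else message("bundle has no raw wideband array")
  if (file.exists(file.path(path, "lfp.f32"))) {
    lfp <- lfpTrace(readF32(file.path(path, "lfp.f32"), meta$n_samples_lfp),
                    fsHz = if (!is.null(meta$fs_lfp_hz)) meta$fs_lfp_hz else 1000,
                    t0S = 0)
  }
  if (file.exists(file.path(path, "rate.f32"))) {
    rate <- ratePath(readF32(file.path(path, "rate.f32"), meta$n_samples_rate),
                     fsHz = 1000, t0S = 0)
  }
  st <- spikeTrain(sort(unique(spikesDf$spike_time_s)), meta$duration_s)
  extraMeta <- meta[setdiff(names(meta), c(bundleMetaKeys, "n_samples_raw",
                                           "n_samples_lfp", "fs_lfp_hz",
                                           "n_samples_rate"))]
  new("SessionBundle", sessionId = meta$session_id, task = meta$task,
      geometry = geometry, events = events, spikes = st, raw = raw,
      lfp = lfp, rate = rate, seed = as.numeric(meta$seed),
      metadata = c(list(fsHz = meta$fs_hz, durationS = meta$duration_s),
                   extraMeta))
}
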