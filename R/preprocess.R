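## ---- zero-phase IIR filtering ------------------------------------------

## steady-state initial filter state for a unit step (transposed direct
## form II), so forward-backward runs start without edge transients
lfilterZi <- function(b, a) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  n <- max(length(a), length(b))
  if (n == 1L) return(numeric(0))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  ## companion matrix of a (transposed), as in the standard lfilter_zi scheme
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

## effective impulse-response length: samples for the slowest pole to decay
## to 1%, capped; drives the reflection padding length
effectiveIrLength <- function(b, a) {
  a <- as.numeric(a)
  if (length(a) < 2) return(32L)
  p <- tryCatch(Mod(polyroot(rev(a / a[1]))), error = function(e) 0.5)
  r <- max(p)
  if (!is.finite(r) || r >= 1) return(10000L)
  max(32L, min(100000L, as.integer(ceiling(log(0.01) / log(r)))))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter `(b, a)` forward and then backward so the net phase
#' response is zero and the effective magnitude response is |H|^2. Edge
#' transients are suppressed by odd-reflection padding (length three times
#' the filter's effective impulse-response length, capped by the signal
#' length) together with steady-state initial conditions scaled to the first
#' padded sample, as in standard filtfilt implementations.
#'
#' @param b,a numerator and denominator filter coefficients.
#' @param x numeric signal.
#' @return Filtered signal, same length as `x`.
#' @examples
#' bf <- signal::butter(4, 0.2)
#' y <- zeroPhaseFilter(bf$b, bf$a, rnorm(512))
#' @export
zeroPhaseFilter <- function(b, a, x) {
  n <- length(x)
  if (n < 2) return(x)
  padlen <- min(n - 1L, 3L * effectiveIrLength(b, a))
  ## odd (point-reflected) extension at both ends
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xp <- c(pre, x, post)
  zi <- lfilterZi(b, a)
  y <- .iirFilterCpp(b, a, xp, zi * xp[1])
  y <- rev(y)
  y <- .iirFilterCpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

## second-order IIR notch biquad (RBJ / iirnotch design): unity gain at DC
## and Nyquist, zero at f0, -3 dB bandwidth f0/q
designNotch <- function(f0, fs, q = 35) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

## keep the input trace class (wideband stays wideband etc.)
sameTrace <- function(template, samples) {
  new(class(template), samples = samples, fsHz = samplingRate(template),
      t0S = startTime(template))
}

#' Line-noise notch filtering
#'
#' Removes the mains fundamental and harmonics with a cascade of second-order
#' IIR notch sections, each applied zero-phase (forward-backward) so the
#' conditioning chain stays lag-free. The quality factor sets the -3 dB notch
#' width (f0/q, about 1.4 Hz at 50 Hz with the default q = 35).
#'
#' @param x a continuous trace ([widebandRecording()] or [lfpTrace()]).
#' @param freqsHz notch center frequencies, Hz.
#' @param q notch quality factor.
#' @return A trace of the same class and sampling rate.
#' @examples
#' rec <- widebandRecording(sin(2 * pi * 50 * (0:3999) / 4000), fsHz = 4000)
#' out <- notchFilter(rec)
#' @export
notchFilter <- function(x, freqsHz = c(50, 100, 150), q = 35) {
  stopifnot(is(x, "ContinuousTrace"), q > 0)
  fs <- samplingRate(x)
  if (any(freqsHz >= fs / 2))
    stop("notch frequency at or above Nyquist")
  s <- samples(x)
  for (f0 in freqsHz) {
    flt <- designNotch(f0, fs, q)
    s <- zeroPhaseFilter(flt$b, flt$a, s)
  }
  sameTrace(x, s)
}

#' Zero-phase low-pass filtering
#'
#' Butterworth low-pass of the given order applied forward-backward: the
#' effective amplitude response is the squared Butterworth magnitude and the
#' phase response is zero (no temporal lag, peak latencies preserved).
#'
#' @param x a continuous trace.
#' @param cutoffHz cutoff frequency, Hz.
#' @param order Butterworth order (of each pass).
#' @return A trace of the same class and sampling rate.
#' @export
lowpassZeroPhase <- function(x, cutoffHz = 300, order = 4) {
  stopifnot(is(x, "ContinuousTrace"))
  fs <- samplingRate(x)
  if (cutoffHz >= fs / 2) stop("cutoff at or above Nyquist")
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "low")
  sameTrace(x, zeroPhaseFilter(bf$b, bf$a, samples(x)))
}

#' Decimate a trace to a lower sampling rate
#'
#' Phase-0 decimation: keeps every (fsIn/fsOut)-th sample starting at sample
#' 0; the caller must have low-passed the signal below fsOut/2 first (as
#' [preprocessChain()] does). The start time is preserved.
#'
#' @param x a continuous trace.
#' @param fsOutHz output sampling rate; must divide the input rate.
#' @return An [lfpTrace()] at `fsOutHz` (a [ratePath()] if the input was one).
#' @export
downsampleTrace <- function(x, fsOutHz = 1000) {
  stopifnot(is(x, "ContinuousTrace"))
  fs <- samplingRate(x)
  dec <- fs / fsOutHz
  if (abs(dec - round(dec)) > 1e-9)
    stop(sprintf("non-integer decimation factor (%g -> %g Hz)", fs, fsOutHz))
  dec <- as.integer(round(dec))
  s <- samples(x)[seq(1, length(samples(x)), by = dec)]
  cls <- if (is(x, "RatePath")) "RatePath" else "LfpTrace"
  new(cls, samples = s, fsHz = as.numeric(fsOutHz), t0S = startTime(x))
}

#' The LFP conditioning chain
#'
#' Applies, in order: IIR notch filters at the mains fundamental and
#' harmonics (zero-phase), a zero-phase Butterworth low-pass at 300 Hz, and
#' decimation to 1 kHz. This is the standard conditioning applied to wideband
#' extracellular voltage before any epoching or measurement.
#'
#' @param x a [widebandRecording()].
#' @param notchFreqsHz,q notch parameters (see [notchFilter()]).
#' @param cutoffHz,order low-pass parameters (see [lowpassZeroPhase()]).
#' @param fsOutHz output rate, Hz.
#' @return An [lfpTrace()] at `fsOutHz`.
#' @examples
#' rec <- widebandRecording(rnorm(8000), fsHz = 8000)
#' lfp <- preprocessChain(rec)
#' samplingRate(lfp)   # 1000
#' @export
preprocessChain <- function(x, notchFreqsHz = c(50, 100, 150), q = 35,
                            cutoffHz = 300, order = 4, fsOutHz = 1000) {
  stopifnot(is(x, "ContinuousTrace"))
  x <- notchFilter(x, notchFreqsHz, q)
  x <- lowpassZeroPhase(x, cutoffHz, order)
  downsampleTrace(x, fsOutHz)
}

#' Spike-density function
#'
#' Continuous firing-rate estimate: each spike contributes a Gaussian density
#' with the given standard deviation (default 10 ms), in units of spikes/s,
#' evaluated on a uniform 1 kHz grid. The kernel is truncated at +/- 5 SD and
#' no edge renormalization is applied (epochs of interest are interior).
#'
#' @param train a [spikeTrain()].
#' @param t0S start of the output grid, seconds.
#' @param durationS length of the output grid, seconds; defaults to the
#'   train's recording duration.
#' @param sdMs Gaussian kernel standard deviation, ms.
#' @param fsHz output grid rate, Hz.
#' @return A [ratePath()].
#' @examples
#' st <- spikeTrain(0.5, durationS = 1)
#' rp <- spikeDensity(st)
#' max(samples(rp))   # ~39.894 sp/s for a 10 ms SD kernel
#' @export
spikeDensity <- function(train, t0S = 0, durationS = NULL, sdMs = 10,
                         fsHz = 1000) {
  stopifnot(is(train, "SpikeTrain"), sdMs > 0)
  if (is.null(durationS)) durationS <- recordingDuration(train) - t0S
  n <- as.integer(round(durationS * fsHz))
  if (n < 1) stop("empty spike-density grid")
  rate <- numeric(n)
  sdS <- sdMs / 1000
  halfW <- as.integer(ceiling(5 * sdS * fsHz))
  for (ts in spikeTimes(train)) {
    c0 <- (ts - t0S) * fsHz             # spike position in grid samples
    i0 <- max(0L, as.integer(ceiling(c0 - halfW)))
    i1 <- min(n - 1L, as.integer(floor(c0 + halfW)))
    if (i1 < i0) next
    idx <- i0:i1
    rate[idx + 1L] <- rate[idx + 1L] +
      stats::dnorm((idx - c0) / fsHz, sd = sdS)
  }
  new("RatePath", samples = rate, fsHz = as.numeric(fsHz),
      t0S = as.numeric(t0S))
}

#' Preprocess a session bundle
#'
#' Runs the conditioning chain on the bundle's raw wideband recording and the
#' spike-density estimator on its spike train, attaching the 1 kHz `lfp` and
#' `rate` signals and recording the filter parameters in the metadata.
#'
#' @param bundle a [SessionBundle] with a raw recording.
#' @inheritParams preprocessChain
#' @param sdMs spike-density kernel SD, ms.
#' @return The bundle with `lfp` and `rate` attached.
#' @export
preprocessSession <- function(bundle, notchFreqsHz = c(50, 100, 150), q = 35,
                              cutoffHz = 300, order = 4, fsOutHz = 1000,
                              sdMs = 10) {
  stopifnot(is(bundle, "SessionBundle"))
  if (is.null(bundle@raw)) stop("bundle has no raw recording to preprocess")
  bundle@lfp <- preprocessChain(bundle@raw, notchFreqsHz, q, cutoffHz, order,
                                fsOutHz)
  bundle@rate <- spikeDensity(bundle@spikes, t0S = startTime(bundle@raw),
                              durationS = length(samples(bundle@raw)) /
                                samplingRate(bundle@raw),
                              sdMs = sdMs, fsHz = fsOutHz)
  bundle@metadata$preprocessing <-
    list(notch_freqs_hz = notchFreqsHz, notch_q = q,
         lowpass_cutoff_hz = cutoffHz, lowpass_order = order,
         fs_out_hz = fsOutHz, spike_density_sd_ms = sdMs,
         zero_phase = TRUE)
  bundle
}
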