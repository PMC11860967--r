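# Threshold-based spike detection on raw voltage traces: zero-phase
# bandpass filtering, robust noise-SD estimation, negative-going crossing
# detection at a configurable multiple of the noise SD.

#' Zero-phase bandpass filter a voltage trace
#'
#' Second-order Butterworth bandpass applied forward and backward
#' (\code{signal::filtfilt}), so spike times suffer no systematic latency
#' shift.
#'
#' @param trace numeric voltage trace.
#' @param params a \linkS4class{DetectorParams}; passband defaults to
#'   4--4000 Hz at a 10 kHz sampling rate.
#' @return Filtered trace, same length.
#' @export
bandpassFilter <- function(trace, params = detectorParams()) {
  stopifnot(is(params, "DetectorParams"))
  validObject(params)
  ny <- params@fs / 2
  bf <- signal::butter(2, c(params@bandpassLow, params@bandpassHigh) / ny,
                       type = "pass")
  if (length(trace) < 3L * (length(bf$a) + length(bf$b)))
    stop("trace shorter than the filter transient")
  as.numeric(signal::filtfilt(bf, trace))
}

#' Estimate the baseline noise SD of a trace
#'
#' Median-absolute-deviation estimate scaled to the Gaussian SD over a
#' calibration window; robust to sparse large spikes contaminating the
#' window.
#'
#' @param trace numeric voltage trace.
#' @param fs sampling frequency in Hz.
#' @param calibrationWindow length of the calibration window in seconds
#'   taken from the start of the trace; \code{Inf} uses the whole trace.
#' @return Noise SD estimate in volts.
#' @export
estimateNoiseSd <- function(trace, fs = 10000, calibrationWindow = Inf) {
  n <- min(length(trace), floor(calibrationWindow * fs))
  if (n < 1L) stop("empty calibration window")
  stats::mad(trace[seq_len(n)], constant = 1.4826)
}

#' Detect spikes as negative threshold crossings
#'
#' A spike is a sample run in which the trace falls to or below
#' \code{-thresholdMultiple * noiseSd} (an event whose peak sits exactly at
#' the threshold is detected). The reported timestamp is the most negative
#' sample within the crossing epoch; events closer than the refractory
#' window are merged onto the first.
#'
#' @param trace numeric (filtered) voltage trace.
#' @param params a \linkS4class{DetectorParams}.
#' @param noiseSd baseline noise SD in volts (> 0).
#' @param electrodeId label for the output train.
#' @return A \linkS4class{SpikeTrain}.
#' @export
detectSpikes <- function(trace, params = detectorParams(), noiseSd,
                         electrodeId = "e1") {
  stopifnot(is(params, "DetectorParams"))
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || !(noiseSd > 0))
    stop("'noiseSd' must be a positive scalar")
  thr <- -params@thresholdMultiple * noiseSd
  below <- trace <= thr
  dur <- length(trace) / params@fs
  if (!any(below))
    return(spikeTrain(numeric(0), duration = dur, electrodeId = electrodeId))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epochs <- which(r$values)
  peakIdx <- vapply(epochs, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.min(trace[seg])]
  }, 0L)
  times <- (peakIdx - 1L) / params@fs
  # merge events within the refractory window onto the first
  if (length(times) > 1L && params@refractory > 0) {
    keep <- c(TRUE, diff(times) >= params@refractory - .TIME_EPS)
    # cumulative merge: compare each event to the last kept one
    last <- times[1]
    for (i in seq_along(times)[-1]) {
      if (times[i] - last < params@refractory - .TIME_EPS) keep[i] <- FALSE
      else last <- times[i]
    }
    times <- times[keep]
  }
  spikeTrain(times[times < dur], duration = dur, electrodeId = electrodeId)
}

#' Full spike detection on a raw trace
#'
#' Convenience composition: bandpass filter, estimate the noise SD on the
#' filtered trace (once per recording), then detect threshold crossings.
#'
#' @param trace raw voltage trace.
#' @param params a \linkS4class{DetectorParams}.
#' @param electrodeId label for the output train.
#' @param calibrationWindow seconds of trace used for noise estimation.
#' @return A \linkS4class{SpikeTrain}.
#' @export
detectSpikesRaw <- function(trace, params = detectorParams(),
                            electrodeId = "e1", calibrationWindow = Inf) {
  f <- bandpassFilter(trace, params)
  sd0 <- estimateNoiseSd(f, fs = params@fs,
                         calibrationWindow = calibrationWindow)
  if (sd0 <= 0) stop("estimated noise SD is zero; cannot set a threshold")
  detectSpikes(f, params, noiseSd = sd0, electrodeId = electrodeId)
}
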