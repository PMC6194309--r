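## Raw trace -> spike times: zero-phase bandpass, robust threshold, and a
## negative-going crossing detector with a refractory dead time.

#' Zero-phase Butterworth bandpass filter
#'
#' Filters the trace with a Butterworth bandpass (default 0.3-6 kHz, fourth
#' order) applied forward and backward (\code{signal::filtfilt}) so the
#' output has zero phase shift; the two passes double the effective order of
#' the designed filter.
#'
#' @param trace a \linkS4class{RawTrace}.
#' @param params a \linkS4class{DetectionParams}.
#' @return a filtered \linkS4class{RawTrace} of the same length and rate.
#' @export
bandpassFilter <- function(trace, params = DetectionParams()) {
  nyq <- trace@sampleRate / 2
  if (params@bandHigh >= nyq)
    stop("bandHigh must be below the Nyquist frequency (", nyq, " Hz)")
  bf <- signal::butter(params@filterOrder,
                       c(params@bandLow, params@bandHigh) / nyq, type = "pass")
  RawTrace(signal::filtfilt(bf, trace@samples), trace@sampleRate)
}

#' Robust spike-detection threshold
#'
#' \deqn{T = -k \, \mathrm{median}(|x| / 0.6745)}
#'
#' The median absolute value over 0.6745 estimates the noise standard
#' deviation robustly (for Gaussian noise it converges to sigma and is
#' nearly insensitive to sparse large spikes), so with the default
#' multiplier k = 4 the threshold sits four noise SDs below zero.
#'
#' @param trace a \linkS4class{RawTrace} (typically bandpass-filtered).
#' @param multiplier k > 0 (default 4).
#' @return negative threshold value.
#' @export
robustThreshold <- function(trace, multiplier = 4) {
  if (length(trace@samples) == 0L) stop("empty trace")
  if (multiplier <= 0) stop("multiplier must be positive")
  -multiplier * median(abs(trace@samples) / 0.6745)
}

#' Detect negative-going threshold crossings
#'
#' A spike is timestamped at the first sample where the trace falls below
#' the (negative) threshold after having been at or above it; crossings
#' closer than \code{deadTime} to the previous accepted spike are discarded.
#'
#' @param trace a filtered \linkS4class{RawTrace}.
#' @param threshold negative threshold, e.g. from
#'   \code{\link{robustThreshold}}.
#' @param deadTime minimum inter-spike interval, ms (default 1).
#' @return sorted numeric vector of spike times, ms.
#' @export
detectSpikes <- function(trace, threshold, deadTime = 1) {
  if (threshold >= 0) stop("threshold must be negative (negative-going detection)")
  x <- trace@samples
  below <- x < threshold
  onset <- which(below & !c(FALSE, below[-length(below)]))
  tms <- (onset - 1L) / trace@sampleRate * 1000
  if (length(tms) <= 1L || deadTime <= 0) return(tms)
  keep <- numeric(length(tms))
  nkeep <- 0L
  last <- -Inf
  for (t in tms) {
    if (t - last >= deadTime) {
      nkeep <- nkeep + 1L
      keep[nkeep] <- t
      last <- t
    }
  }
  keep[seq_len(nkeep)]
}

#' Full detection stage: filter, threshold, detect
#'
#' Convenience wrapper chaining \code{\link{bandpassFilter}},
#' \code{\link{robustThreshold}} and \code{\link{detectSpikes}}.
#'
#' @param trace a raw \linkS4class{RawTrace}.
#' @param params a \linkS4class{DetectionParams}.
#' @return list with \code{spikeTimes} (ms), \code{threshold} and the
#'   \code{filtered} trace.
#' @export
detectFromRaw <- function(trace, params = DetectionParams()) {
  filt <- bandpassFilter(trace, params)
  thr <- robustThreshold(filt, params@thresholdMultiplier)
  list(spikeTimes = detectSpikes(filt, thr, params@deadTime),
       threshold = thr, filtered = filt)
}
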