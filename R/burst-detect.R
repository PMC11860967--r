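# Max-interval burst detection: scan -> merge -> filter.
#
# Comparison conventions (pinned by tests): "maximum"/"minimum" thresholds
# are inclusive (ISI <= max, duration >= min, spikes >= min); merging uses a
# strict gap < minIbi. All time comparisons carry an absolute 1e-9 s
# tolerance so boundary inputs on ms grids are classified by intent rather
# than by floating-point rounding.

.emptyBursts <- function() {
  data.frame(firstIndex = integer(0), lastIndex = integer(0),
             onset = numeric(0), offset = numeric(0),
             duration = numeric(0), nSpikes = integer(0))
}

.makeBursts <- function(times, first, last) {
  data.frame(firstIndex = as.integer(first), lastIndex = as.integer(last),
             onset = times[first], offset = times[last],
             duration = times[last] - times[first],
             nSpikes = as.integer(last - first + 1L))
}

#' Scan a spike train for candidate bursts
#'
#' A candidate burst begins at the first spike of a pair whose interspike
#' interval is within \code{maxBeginIsi} and extends over subsequent spikes
#' while intervals stay within \code{maxEndIsi}. Candidates are maximal and
#' disjoint.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param params a \linkS4class{BurstParams}.
#' @return data.frame with columns firstIndex, lastIndex, onset, offset,
#'   duration, nSpikes (possibly zero rows).
#' @export
scanBursts <- function(train, params = burstParams()) {
  stopifnot(is(train, "SpikeTrain"), is(params, "BurstParams"))
  t <- spikeTimes(train)
  n <- length(t)
  if (n < 2L) return(.emptyBursts())
  d <- diff(t)
  beginOk <- d <= params@maxBeginIsi + .TIME_EPS
  extendOk <- d <= params@maxEndIsi + .TIME_EPS
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i < n) {
    if (beginOk[i]) {
      j <- i + 1L
      while (j < n && extendOk[j]) j <- j + 1L
      first <- c(first, i); last <- c(last, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  .makeBursts(t, first, last)
}

#' Merge candidate bursts separated by short gaps
#'
#' Consecutive candidates whose gap (next onset minus previous offset) is
#' strictly below \code{minIbi} are merged, together with any interior
#' spikes, until no mergeable pair remains.
#'
#' @param candidates candidate burst data.frame from \code{\link{scanBursts}}.
#' @param params a \linkS4class{BurstParams}.
#' @param train the \linkS4class{SpikeTrain} the candidates came from.
#' @return Merged burst data.frame.
#' @export
mergeBursts <- function(candidates, params = burstParams(), train) {
  stopifnot(is(params, "BurstParams"), is(train, "SpikeTrain"))
  if (nrow(candidates) < 2L) return(candidates)
  t <- spikeTimes(train)
  first <- candidates$firstIndex; last <- candidates$lastIndex
  outF <- first[1]; outL <- last[1]
  for (k in seq_len(nrow(candidates))[-1]) {
    gap <- t[first[k]] - t[outL[length(outL)]]
    if (gap < params@minIbi - .TIME_EPS) {
      outL[length(outL)] <- last[k]
    } else {
      outF <- c(outF, first[k]); outL <- c(outL, last[k])
    }
  }
  .makeBursts(t, outF, outL)
}

#' Filter merged bursts by duration and spike count
#'
#' Keeps bursts lasting at least \code{minDuration} seconds and containing
#' at least \code{minSpikes} spikes.
#'
#' @param bursts merged burst data.frame.
#' @param params a \linkS4class{BurstParams}.
#' @return Filtered burst data.frame.
#' @export
filterBursts <- function(bursts, params = burstParams()) {
  stopifnot(is(params, "BurstParams"))
  keep <- bursts$duration >= params@minDuration - .TIME_EPS &
    bursts$nSpikes >= params@minSpikes
  out <- bursts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect bursts in a spike train (max-interval method)
#'
#' Composition \code{scanBursts} then \code{mergeBursts} then
#' \code{filterBursts}. Deterministic; every reported burst satisfies the
#' duration and spike-count thresholds, and bursts are disjoint and ordered.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param params a \linkS4class{BurstParams} (defaults 0.1 s begin ISI,
#'   0.2 s end ISI, 0.5 s IBI, 0.05 s duration, 6 spikes).
#' @return data.frame with columns firstIndex, lastIndex, onset, offset,
#'   duration, nSpikes.
#' @examples
#' st <- spikeTrain(seq(0, 0.25, by = 0.05), duration = 10)
#' detectBursts(st)
#' @export
detectBursts <- function(train, params = burstParams()) {
  out <- filterBursts(mergeBursts(scanBursts(train, params), params, train),
                      params)
  stopifnot(all(out$duration >= params@minDuration - .TIME_EPS),
            all(out$nSpikes >= params@minSpikes))
  out
}
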