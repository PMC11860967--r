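# Synthetic MEA plate generator: background Poisson firing plus Poisson
# bursting episodes with programmable multiplicative treatment effects.

#' Generate a homogeneous Poisson spike train
#'
#' @param rate firing rate in events/s (>= 0).
#' @param duration recording window in seconds.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param electrodeId electrode label for the resulting train.
#' @return A \linkS4class{SpikeTrain} with strictly increasing times in
#'   \code{[0, duration)}.
#' @examples
#' generatePoissonTrain(2, 60, seed = 1)
#' @export
generatePoissonTrain <- function(rate, duration, seed, electrodeId = "e1") {
  .assertScalarNum(rate, "rate", min = 0)
  .assertScalarNum(duration, "duration", min = 0, strict = TRUE)
  times <- withSeed(seed, {
    n <- stats::rpois(1L, rate * duration)
    sort(stats::runif(n, 0, duration))
  })
  spikeTrain(times, duration = duration, electrodeId = electrodeId)
}

#' Generate a bursting spike train with ground-truth annotations
#'
#' Superimposes burst episodes on background Poisson firing. Burst onsets
#' follow a Poisson process at \code{burstRate}; each burst carries
#' \code{1 + Poisson(mean - 1)} spikes at the fixed within-burst interval,
#' so no burst is empty. Bursts running past the recording end are
#' truncated and flagged; overlapping episodes are merged into a single
#' annotation interval, since no interval-based detector can separate them.
#'
#' @param spec a \linkS4class{TrainGenSpec}.
#' @param seed integer seed.
#' @param electrodeId electrode label.
#' @return A \linkS4class{SpikeTrain} with attribute \code{"annotations"}, a
#'   data.frame with columns onset, offset, nSpikes, truncated (one row per
#'   merged ground-truth burst interval).
#' @export
generateBurstingTrain <- function(spec, seed, electrodeId = "e1") {
  stopifnot(is(spec, "TrainGenSpec"))
  validObject(spec)
  dur <- spec@duration
  if (spec@burstRate == 0) {
    # degenerates exactly to the background Poisson generator (no burst
    # draws touch the RNG stream)
    out <- generatePoissonTrain(spec@backgroundRate, dur, seed = seed,
                                electrodeId = electrodeId)
    attr(out, "annotations") <- data.frame(
      onset = numeric(0), offset = numeric(0), nSpikes = integer(0),
      truncated = logical(0))
    return(out)
  }
  res <- withSeed(seed, {
    nb <- stats::rpois(1L, spec@burstRate / 60 * dur)
    onsets <- sort(stats::runif(nb, 0, dur))
    counts <- 1L + stats::rpois(nb, spec@spikesPerBurstMean - 1)
    # spike times of all bursts at once: onset[i] + (0:(counts[i]-1)) * isi
    idx <- sequence(counts) - 1L
    s <- rep.int(onsets, counts) + idx * spec@intraBurstIsi
    keep <- s < dur
    bid <- rep.int(seq_len(nb), counts)[keep]
    s <- s[keep]
    kept <- tabulate(bid, nbins = nb)
    ann <- data.frame(
      onset = onsets[kept > 0L],
      offset = vapply(which(kept > 0L), function(i)
        onsets[i] + (kept[i] - 1L) * spec@intraBurstIsi, 0),
      nSpikes = kept[kept > 0L],
      truncated = (kept < counts)[kept > 0L])
    nbg <- stats::rpois(1L, spec@backgroundRate * dur)
    bg <- sort(stats::runif(nbg, 0, dur))
    list(times = sort(unique(c(s, bg))), ann = ann)
  })
  ann <- res$ann
  if (nrow(ann) > 1L) {
    # merge overlapping/abutting annotation intervals (vector scan over
    # cumulative maxima of the offsets)
    newGrp <- c(TRUE, ann$onset[-1] > cummax(ann$offset)[-nrow(ann)])
    grp <- cumsum(newGrp)
    ann <- data.frame(
      onset = tapply(ann$onset, grp, min),
      offset = tapply(ann$offset, grp, max),
      nSpikes = as.integer(tapply(ann$nSpikes, grp, sum)),
      truncated = as.logical(tapply(ann$truncated, grp, any)))
    rownames(ann) <- NULL
  }
  out <- spikeTrain(res$times, duration = dur, electrodeId = electrodeId)
  attr(out, "annotations") <- ann
  out
}

#' Apply a treatment effect to a generator spec
#'
#' Pure function: background rate is scaled by \code{firingRateScale}, the
#' mean spikes per burst by \code{spikesPerBurstScale}, and the within-burst
#' interspike interval by \code{burstDurationScale} (burst duration is
#' approximately \code{(n - 1) * isi}, so scaling the interval scales the
#' duration while leaving the spike count untouched).
#'
#' @param spec a \linkS4class{TrainGenSpec}.
#' @param effect a \linkS4class{TreatmentEffect}.
#' @return The scaled \linkS4class{TrainGenSpec}.
#' @export
applyEffect <- function(spec, effect) {
  stopifnot(is(spec, "TrainGenSpec"), is(effect, "TreatmentEffect"))
  trainGenSpec(
    backgroundRate = spec@backgroundRate * effect@firingRateScale,
    burstRate = spec@burstRate,
    spikesPerBurstMean = max(1, spec@spikesPerBurstMean * effect@spikesPerBurstScale),
    intraBurstIsi = spec@intraBurstIsi * effect@burstDurationScale,
    duration = spec@duration)
}

#' Generate a whole synthetic MEA plate
#'
#' Produces one \linkS4class{RecordingSession} per (well, timepoint).
#' Treatment effects act only at and after their onset timepoint (by
#' position in the plate's ordered timepoint labels). Each electrode's seed
#' is derived deterministically from the master seed and the (well,
#' timepoint, electrode) labels, so regeneration is exactly reproducible
#' without any seed bookkeeping.
#'
#' @param plate a \linkS4class{PlateSpec}.
#' @return An \linkS4class{MEAPlate}.
#' @export
generatePlate <- function(plate) {
  stopifnot(is(plate, "PlateSpec"))
  validObject(plate)
  tps <- plate@timepoints
  sessionList <- list()
  truth <- list()
  effspec <- list()
  for (w in plate@wells) {
    gen0 <- plate@genSpecs[[w]]
    eff <- plate@effects[[w]]
    onsetIdx <- match(eff@onsetTimepoint, tps)
    for (ti in seq_along(tps)) {
      tp <- tps[ti]
      gen <- if (!is.na(onsetIdx) && ti >= onsetIdx) applyEffect(gen0, eff)
             else gen0
      trs <- vector("list", plate@electrodesPerWell)
      for (e in seq_len(plate@electrodesPerWell)) {
        eid <- sprintf("el%02d", e)
        sd_e <- hashSeed(plate@masterSeed, w, tp, eid)
        tr <- generateBurstingTrain(gen, seed = sd_e, electrodeId = eid)
        ann <- attr(tr, "annotations")
        if (nrow(ann))
          truth[[length(truth) + 1L]] <-
            cbind(well = w, timepoint = tp, electrode = eid, ann)
        attr(tr, "annotations") <- NULL
        trs[[e]] <- tr
      }
      sessionList[[paste(w, tp, sep = ".")]] <-
        recordingSession(w, tp, trains = trs, label = plate@labels[[w]],
                         duration = gen@duration)
      effspec[[length(effspec) + 1L]] <- data.frame(
        well = w, timepoint = tp, label = plate@labels[[w]],
        backgroundRate = gen@backgroundRate, burstRate = gen@burstRate,
        spikesPerBurstMean = gen@spikesPerBurstMean,
        intraBurstIsi = gen@intraBurstIsi)
    }
  }
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(well = character(0), timepoint = character(0),
               electrode = character(0), onset = numeric(0),
               offset = numeric(0), nSpikes = integer(0),
               truncated = logical(0))
  rownames(truthDf) <- NULL
  new("MEAPlate", sessions = sessionList, truth = truthDf,
      effectiveSpecs = do.call(rbind, effspec), spec = plate)
}

#' Generate a correlated copy of a spike train
#'
#' The copy is the base train with independent Gaussian time jitter and
#' independent thinning, re-sorted and clipped to the recording window —
#' a controllable-synchrony test harness for the pairwise synchrony score.
#'
#' @param base a \linkS4class{SpikeTrain}.
#' @param jitterSd SD of the Gaussian jitter, seconds (>= 0).
#' @param deletionProb probability of dropping each spike (in [0, 1)).
#' @param seed integer seed.
#' @return A list with elements \code{a} (the base train) and \code{b}
#'   (the jittered copy).
#' @export
generateCorrelatedPair <- function(base, jitterSd = 0, deletionProb = 0,
                                   seed = 1) {
  stopifnot(is(base, "SpikeTrain"), jitterSd >= 0,
            deletionProb >= 0, deletionProb < 1)
  t2 <- withSeed(seed, {
    t <- spikeTimes(base)
    if (deletionProb > 0) t <- t[stats::runif(length(t)) >= deletionProb]
    if (jitterSd > 0) t <- t + stats::rnorm(length(t), 0, jitterSd)
    sort(t[t >= 0 & t < base@duration])
  })
  list(a = base,
       b = spikeTrain(unique(t2), duration = base@duration,
                      electrodeId = paste0(base@electrodeId, "_jit")))
}

#' Stereotyped extracellular spike waveform template
#'
#' A 1-ms biphasic template with a dominant negative phase followed by a
#' smaller positive rebound, normalized so its most negative sample is
#' exactly -1.
#'
#' @param fs sampling frequency in Hz.
#' @return Numeric waveform vector.
#' @export
spikeTemplate <- function(fs = 10000) {
  n <- max(3L, round(fs * 0.001))
  tt <- seq(0, 0.001, length.out = n)
  w <- -exp(-((tt - 0.00040) / 0.00025)^2) +
    0.3 * exp(-((tt - 0.00085) / 0.00012)^2)
  w / -min(w)  # most negative sample maps to exactly -1
}

#' Add spike waveforms to a voltage trace
#'
#' @param trace numeric voltage trace.
#' @param times spike times in seconds.
#' @param amplitude peak (absolute) amplitude of the negative phase, volts.
#' @param fs sampling frequency in Hz.
#' @return The trace with one template per timestamp added; templates of
#'   spikes closer than one waveform width are summed.
#' @export
injectSpikes <- function(trace, times, amplitude, fs = 10000) {
  tpl <- amplitude * spikeTemplate(fs)
  for (tm in times) {
    i0 <- round(tm * fs) + 1L
    idx <- i0:(i0 + length(tpl) - 1L)
    ok <- idx >= 1L & idx <= length(trace)
    trace[idx[ok]] <- trace[idx[ok]] + tpl[ok]
  }
  trace
}

#' Generate a raw voltage trace for a spike train
#'
#' Zero-mean Gaussian noise of the given SD with a stereotyped biphasic
#' spike waveform (dominant negative phase, peak \code{spikeAmplitude}
#' noise SDs deep) at every timestamp.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param spikeAmplitude spike peak amplitude in multiples of the noise SD.
#' @param noiseSd noise standard deviation in volts.
#' @param fs sampling frequency in Hz (default 10000).
#' @param seed integer seed for the noise.
#' @return Numeric trace of length \code{round(duration * fs)}.
#' @export
generateRawTrace <- function(train, spikeAmplitude = 8, noiseSd = 1e-5,
                             fs = 10000, seed = 1) {
  stopifnot(is(train, "SpikeTrain"), fs > 0, spikeAmplitude >= 0)
  n <- round(train@duration * fs)
  trace <- withSeed(seed, stats::rnorm(n, 0, noiseSd))
  if (spikeAmplitude > 0 && nSpikes(train) > 0)
    trace <- injectSpikes(trace, spikeTimes(train),
                          spikeAmplitude * noiseSd, fs = fs)
  trace
}
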