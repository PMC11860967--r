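#' @import methods
NULL

#' SpikeTrain: sorted spike timestamps for one electrode
#'
#' Holds the action-potential timestamps (seconds from recording start) of a
#' single electrode over one recording window. Times must be strictly
#' increasing and lie in \code{[0, duration)}.
#'
#' @slot electrodeId character label of the electrode.
#' @slot times numeric vector of spike times in seconds, strictly increasing.
#' @slot duration length of the recording window in seconds (default 1800,
#'   i.e. a 30-min recording).
#' @export
setClass("SpikeTrain",
  representation(electrodeId = "character", times = "numeric",
                 duration = "numeric"),
  prototype(electrodeId = "e1", times = numeric(0), duration = 1800))

setValidity("SpikeTrain", function(object) {
  msgs <- character(0)
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0)
    msgs <- c(msgs, "duration must be a positive finite scalar")
  t <- object@times
  if (anyNA(t) || any(!is.finite(t)))
    msgs <- c(msgs, "times must be finite")
  else {
    if (is.unsorted(t, strictly = TRUE))
      msgs <- c(msgs, sprintf("times of electrode '%s' must be strictly increasing",
                              object@electrodeId))
    if (length(t) && (t[1] < 0 || t[length(t)] >= object@duration))
      msgs <- c(msgs, sprintf("times of electrode '%s' must lie in [0, duration)",
                              object@electrodeId))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpikeTrain
#'
#' Duplicated timestamps are collapsed (with a warning) so that downstream
#' detectors can assume strict ordering.
#'
#' @param times numeric spike times in seconds.
#' @param duration recording window length in seconds.
#' @param electrodeId electrode label.
#' @param sort sort the times before validation (a warning is emitted when
#'   reordering was actually needed).
#' @return A \linkS4class{SpikeTrain}.
#' @examples
#' st <- spikeTrain(c(0.1, 0.25, 1.3), duration = 60)
#' nSpikes(st)
#' @export
spikeTrain <- function(times = numeric(0), duration = 1800,
                       electrodeId = "e1", sort = FALSE) {
  times <- as.numeric(times)
  if (sort && is.unsorted(times)) {
    warning(sprintf("electrode '%s': times were not sorted; reordering",
                    electrodeId))
    times <- sort(times)
  }
  if (anyDuplicated(times)) {
    warning(sprintf("electrode '%s': duplicated timestamps collapsed",
                    electrodeId))
    times <- unique(times)
  }
  new("SpikeTrain", electrodeId = as.character(electrodeId), times = times,
      duration = as.numeric(duration))
}

#' RecordingSession: all electrode trains of one well at one timepoint
#'
#' @slot wellId well label.
#' @slot timepoint timepoint label (e.g. "baseline", "30m", "7D").
#' @slot label condition label of the well (e.g. "control").
#' @slot treatment named numeric vector mapping cytokine name to
#'   concentration (pg/mL); may be empty.
#' @slot trains list of \linkS4class{SpikeTrain}, unique electrode ids,
#'   all sharing the session's recording duration.
#' @slot duration recording duration in seconds.
#' @export
setClass("RecordingSession",
  representation(wellId = "character", timepoint = "character",
                 label = "character", treatment = "numeric",
                 trains = "list", duration = "numeric"),
  prototype(wellId = "w1", timepoint = "baseline", label = "control",
            treatment = numeric(0), trains = list(), duration = 1800))

setValidity("RecordingSession", function(object) {
  msgs <- character(0)
  if (!all(vapply(object@trains, is, TRUE, "SpikeTrain")))
    msgs <- c(msgs, "trains must all be SpikeTrain objects")
  else {
    ids <- vapply(object@trains, function(x) x@electrodeId, "")
    if (anyDuplicated(ids))
      msgs <- c(msgs, "electrode ids must be unique within a session")
    durs <- vapply(object@trains, function(x) x@duration, 0)
    if (length(durs) && any(durs != object@duration))
      msgs <- c(msgs, "all trains must share the session recording duration")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RecordingSession
#' @param wellId,timepoint,label,treatment,trains,duration see the class slots.
#' @return A \linkS4class{RecordingSession}.
#' @export
recordingSession <- function(wellId, timepoint, trains = list(),
                             label = "control", treatment = numeric(0),
                             duration = 1800) {
  new("RecordingSession", wellId = as.character(wellId),
      timepoint = as.character(timepoint), label = as.character(label),
      treatment = treatment, trains = trains, duration = as.numeric(duration))
}

#' TrainGenSpec: parameters of the synthetic spike-train generator
#'
#' Describes one electrode's activity as background Poisson firing overlaid
#' with bursting episodes whose onsets are themselves Poisson.
#'
#' @slot backgroundRate background firing rate, events/s.
#' @slot burstRate burst onset rate, bursts/min.
#' @slot spikesPerBurstMean mean spikes per burst (>= 1).
#' @slot intraBurstIsi interspike interval inside a burst, seconds.
#' @slot duration recording duration, seconds.
#' @export
setClass("TrainGenSpec",
  representation(backgroundRate = "numeric", burstRate = "numeric",
                 spikesPerBurstMean = "numeric", intraBurstIsi = "numeric",
                 duration = "numeric"),
  prototype(backgroundRate = 0.5, burstRate = 10, spikesPerBurstMean = 8,
            intraBurstIsi = 0.02, duration = 1800))

setValidity("TrainGenSpec", function(object) {
  msgs <- character(0)
  for (s in c("backgroundRate", "burstRate", "spikesPerBurstMean",
              "intraBurstIsi", "duration")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) msgs <- c(msgs, paste(s, "must be a finite scalar"))
  }
  if (!length(msgs)) {
    if (object@backgroundRate < 0) msgs <- c(msgs, "backgroundRate must be >= 0")
    if (object@burstRate < 0) msgs <- c(msgs, "burstRate must be >= 0")
    if (object@spikesPerBurstMean < 1) msgs <- c(msgs, "spikesPerBurstMean must be >= 1")
    if (object@intraBurstIsi <= 0) msgs <- c(msgs, "intraBurstIsi must be > 0")
    if (object@duration <= 0) msgs <- c(msgs, "duration must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TrainGenSpec
#' @param backgroundRate events/s (>= 0).
#' @param burstRate bursts/min (>= 0).
#' @param spikesPerBurstMean mean spike count per burst (>= 1).
#' @param intraBurstIsi within-burst interspike interval in seconds.
#' @param duration recording duration in seconds.
#' @return A \linkS4class{TrainGenSpec}.
#' @export
trainGenSpec <- function(backgroundRate = 0.5, burstRate = 10,
                         spikesPerBurstMean = 8, intraBurstIsi = 0.02,
                         duration = 1800) {
  new("TrainGenSpec", backgroundRate = backgroundRate, burstRate = burstRate,
      spikesPerBurstMean = spikesPerBurstMean, intraBurstIsi = intraBurstIsi,
      duration = duration)
}

#' TreatmentEffect: multiplicative effect of a treatment on activity
#'
#' Scale factors of 1 mean no effect. The burst-duration effect acts on the
#' within-burst interspike interval (holding spike count), so burst duration
#' and spikes-per-burst are separately identifiable observables.
#'
#' @slot burstDurationScale multiplier on burst duration (> 0).
#' @slot firingRateScale multiplier on background firing rate (> 0).
#' @slot spikesPerBurstScale multiplier on mean spikes per burst (> 0).
#' @slot onsetTimepoint label of the first timepoint at which the effect acts.
#' @export
setClass("TreatmentEffect",
  representation(burstDurationScale = "numeric", firingRateScale = "numeric",
                 spikesPerBurstScale = "numeric", onsetTimepoint = "character"),
  prototype(burstDurationScale = 1, firingRateScale = 1,
            spikesPerBurstScale = 1, onsetTimepoint = "30m"))

setValidity("TreatmentEffect", function(object) {
  sc <- c(object@burstDurationScale, object@firingRateScale,
          object@spikesPerBurstScale)
  if (any(!is.finite(sc)) || any(sc <= 0))
    "all scale factors must be finite and > 0"
  else TRUE
})

#' Construct a TreatmentEffect
#' @param burstDurationScale,firingRateScale,spikesPerBurstScale positive
#'   multipliers; 1 = no effect.
#' @param onsetTimepoint label of the first affected timepoint.
#' @return A \linkS4class{TreatmentEffect}.
#' @export
treatmentEffect <- function(burstDurationScale = 1, firingRateScale = 1,
                            spikesPerBurstScale = 1, onsetTimepoint = "30m") {
  new("TreatmentEffect", burstDurationScale = burstDurationScale,
      firingRateScale = firingRateScale,
      spikesPerBurstScale = spikesPerBurstScale,
      onsetTimepoint = as.character(onsetTimepoint))
}

#' PlateSpec: design of a synthetic multi-well MEA plate experiment
#'
#' @slot wells character vector of well ids.
#' @slot labels named character vector: condition label per well.
#' @slot genSpecs named list of \linkS4class{TrainGenSpec}, one per well.
#' @slot effects named list of \linkS4class{TreatmentEffect}, one per well.
#' @slot electrodesPerWell electrodes per well.
#' @slot timepoints ordered, unique timepoint labels.
#' @slot masterSeed integer master seed; per-electrode seeds are derived from
#'   it deterministically.
#' @export
setClass("PlateSpec",
  representation(wells = "character", labels = "character",
                 genSpecs = "list", effects = "list",
                 electrodesPerWell = "integer", timepoints = "character",
                 masterSeed = "integer"))

setValidity("PlateSpec", function(object) {
  msgs <- character(0)
  if (!length(object@timepoints) || anyDuplicated(object@timepoints))
    msgs <- c(msgs, "timepoints must be non-empty and unique")
  if (anyDuplicated(object@wells))
    msgs <- c(msgs, "well ids must be unique")
  for (nm in c("labels", "genSpecs", "effects")) {
    if (!setequal(names(slot(object, nm)), object@wells))
      msgs <- c(msgs, sprintf("'%s' must be named by the well ids", nm))
  }
  if (object@electrodesPerWell < 1L)
    msgs <- c(msgs, "electrodesPerWell must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PlateSpec
#'
#' @param conditions named list, one entry per well, each a list with
#'   elements \code{gen} (a \linkS4class{TrainGenSpec}), \code{effect}
#'   (a \linkS4class{TreatmentEffect}; optional, defaults to no effect) and
#'   \code{label} (condition label; optional, defaults to "control").
#' @param electrodesPerWell electrodes per well (default 16).
#' @param timepoints ordered timepoint labels; the default mirrors a design
#'   with a pre-dose baseline, two first-hour recordings and 1/2/7-day
#'   follow-ups.
#' @param masterSeed integer master seed.
#' @return A \linkS4class{PlateSpec}.
#' @export
plateSpec <- function(conditions, electrodesPerWell = 16,
                      timepoints = c("baseline", "30m", "60m", "1D", "2D", "7D"),
                      masterSeed = 1) {
  wells <- names(conditions)
  if (is.null(wells) || anyDuplicated(wells))
    stop("'conditions' must be a uniquely named list (one entry per well)")
  gen <- lapply(conditions, function(x) x$gen)
  eff <- lapply(conditions, function(x) {
    if (is.null(x$effect)) treatmentEffect() else x$effect
  })
  lab <- vapply(conditions, function(x) {
    if (is.null(x$label)) "control" else as.character(x$label)
  }, "")
  new("PlateSpec", wells = wells, labels = lab, genSpecs = gen, effects = eff,
      electrodesPerWell = as.integer(electrodesPerWell),
      timepoints = as.character(timepoints),
      masterSeed = as.integer(masterSeed))
}

#' Two-arm plate design helper
#'
#' Convenience constructor for the common control-vs-treated design: the
#' first \code{nPerArm} wells are untreated controls, the next \code{nPerArm}
#' carry \code{effect} from its onset timepoint onwards. Both arms share the
#' same baseline generator.
#'
#' @param gen baseline \linkS4class{TrainGenSpec} shared by all wells.
#' @param effect \linkS4class{TreatmentEffect} applied to the treated arm.
#' @param nPerArm wells per arm (default 6).
#' @param ... passed to \code{\link{plateSpec}}.
#' @return A \linkS4class{PlateSpec}.
#' @export
twoArmPlateSpec <- function(gen = trainGenSpec(), effect = treatmentEffect(),
                            nPerArm = 6, ...) {
  conds <- c(
    setNames(lapply(seq_len(nPerArm), function(i)
      list(gen = gen, label = "control")),
      sprintf("C%02d", seq_len(nPerArm))),
    setNames(lapply(seq_len(nPerArm), function(i)
      list(gen = gen, effect = effect, label = "treated")),
      sprintf("T%02d", seq_len(nPerArm))))
  plateSpec(conds, ...)
}

#' MEAPlate: a generated plate with its ground truth
#'
#' Result of \code{\link{generatePlate}}: one \linkS4class{RecordingSession}
#' per (well, timepoint) plus the generator's burst annotations and the
#' effective (post-effect) generator parameters, for parameter-recovery
#' studies.
#'
#' @slot sessions list of \linkS4class{RecordingSession}.
#' @slot truth data.frame of ground-truth burst annotations (well, timepoint,
#'   electrode, onset, offset, nSpikes, truncated).
#' @slot effectiveSpecs data.frame of the effective generator parameters per
#'   (well, timepoint).
#' @slot spec the \linkS4class{PlateSpec} used.
#' @export
setClass("MEAPlate",
  representation(sessions = "list", truth = "data.frame",
                 effectiveSpecs = "data.frame", spec = "PlateSpec"))

#' BurstParams: max-interval burst detector parameters
#'
#' The defaults are the standard max-interval settings for cortical cultures:
#' a burst starts at a spike pair closer than \code{maxBeginIsi}, extends
#' while interspike intervals stay within \code{maxEndIsi}, bursts separated
#' by less than \code{minIbi} are merged, and merged bursts must last at
#' least \code{minDuration} and contain at least \code{minSpikes} spikes.
#'
#' @slot maxBeginIsi seconds (default 0.1).
#' @slot maxEndIsi seconds (default 0.2).
#' @slot minIbi seconds (default 0.5).
#' @slot minDuration seconds (default 0.05).
#' @slot minSpikes count (default 6).
#' @export
setClass("BurstParams",
  representation(maxBeginIsi = "numeric", maxEndIsi = "numeric",
                 minIbi = "numeric", minDuration = "numeric",
                 minSpikes = "integer"),
  prototype(maxBeginIsi = 0.1, maxEndIsi = 0.2, minIbi = 0.5,
            minDuration = 0.05, minSpikes = 6L))

setValidity("BurstParams", function(object) {
  msgs <- character(0)
  v <- c(object@maxBeginIsi, object@maxEndIsi, object@minIbi,
         object@minDuration)
  if (any(!is.finite(v)) || any(v <= 0))
    msgs <- c(msgs, "all interval parameters must be positive")
  if (object@maxBeginIsi > object@maxEndIsi)
    msgs <- c(msgs, "maxBeginIsi must be <= maxEndIsi")
  if (object@minSpikes < 2L)
    msgs <- c(msgs, "minSpikes must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' Construct BurstParams
#' @param maxBeginIsi,maxEndIsi,minIbi,minDuration,minSpikes see the class
#'   documentation; defaults (0.1, 0.2, 0.5, 0.05, 6).
#' @return A \linkS4class{BurstParams}.
#' @export
burstParams <- function(maxBeginIsi = 0.1, maxEndIsi = 0.2, minIbi = 0.5,
                        minDuration = 0.05, minSpikes = 6) {
  new("BurstParams", maxBeginIsi = maxBeginIsi, maxEndIsi = maxEndIsi,
      minIbi = minIbi, minDuration = minDuration,
      minSpikes = as.integer(minSpikes))
}

#' DetectorParams: spike-detection parameters
#'
#' Spikes are negative-going threshold crossings of the bandpass-filtered
#' trace at \code{thresholdMultiple} times the baseline noise SD.
#'
#' @slot thresholdMultiple threshold in multiples of the noise SD (default 6.5).
#' @slot bandpassLow,bandpassHigh passband edges in Hz (defaults 4 and 4000).
#' @slot refractory merge window for crossings, seconds (default 0.001).
#' @slot fs sampling frequency in Hz (default 10000).
#' @export
setClass("DetectorParams",
  representation(thresholdMultiple = "numeric", bandpassLow = "numeric",
                 bandpassHigh = "numeric", refractory = "numeric",
                 fs = "numeric"),
  prototype(thresholdMultiple = 6.5, bandpassLow = 4, bandpassHigh = 4000,
            refractory = 0.001, fs = 10000))

setValidity("DetectorParams", function(object) {
  msgs <- character(0)
  if (object@thresholdMultiple <= 0)
    msgs <- c(msgs, "thresholdMultiple must be > 0")
  if (!(object@bandpassLow > 0 && object@bandpassLow < object@bandpassHigh &&
        object@bandpassHigh < object@fs / 2))
    msgs <- c(msgs, "need 0 < bandpassLow < bandpassHigh < fs/2")
  if (object@refractory < 0)
    msgs <- c(msgs, "refractory must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct DetectorParams
#' @param thresholdMultiple,bandpassLow,bandpassHigh,refractory,fs see the
#'   class documentation.
#' @return A \linkS4class{DetectorParams}.
#' @export
detectorParams <- function(thresholdMultiple = 6.5, bandpassLow = 4,
                           bandpassHigh = 4000, refractory = 0.001,
                           fs = 10000) {
  new("DetectorParams", thresholdMultiple = thresholdMultiple,
      bandpassLow = bandpassLow, bandpassHigh = bandpassHigh,
      refractory = refractory, fs = fs)
}

#' FilterParams: electrode inclusion/exclusion rules
#'
#' An electrode is \emph{inactive} if it recorded fewer than
#' \code{minActiveSpikes} spikes in the recording window, and \emph{noisy}
#' if its mean burst duration exceeds \code{noisyMeanBurstDuration}
#' (strictly greater). Remaining electrodes are \emph{included}.
#'
#' @slot minActiveSpikes count (default 10).
#' @slot noisyMeanBurstDuration seconds (default 5).
#' @export
setClass("FilterParams",
  representation(minActiveSpikes = "integer",
                 noisyMeanBurstDuration = "numeric"),
  prototype(minActiveSpikes = 10L, noisyMeanBurstDuration = 5))

setValidity("FilterParams", function(object) {
  if (object@minActiveSpikes <= 0L || object@noisyMeanBurstDuration <= 0)
    "both parameters must be positive" else TRUE
})

#' Construct FilterParams
#' @param minActiveSpikes,noisyMeanBurstDuration see the class documentation.
#' @return A \linkS4class{FilterParams}.
#' @export
filterParams <- function(minActiveSpikes = 10, noisyMeanBurstDuration = 5) {
  new("FilterParams", minActiveSpikes = as.integer(minActiveSpikes),
      noisyMeanBurstDuration = noisyMeanBurstDuration)
}

#' SurrogateSpec: surrogate normalization settings for synchrony scores
#'
#' Raw similarity scores are normalized by the mean similarity of
#' rate-matched independent Poisson surrogate pairs, which removes the
#' density bias of the underlying distance (denser trains otherwise score
#' as more similar by chance).
#'
#' @slot nSurrogates number of surrogate pairs (default 20).
#' @slot seed integer seed for the surrogate stream.
#' @export
setClass("SurrogateSpec",
  representation(nSurrogates = "integer", seed = "integer"),
  prototype(nSurrogates = 20L, seed = 1L))

setValidity("SurrogateSpec", function(object) {
  if (object@nSurrogates < 1L) "nSurrogates must be >= 1" else TRUE
})

#' Construct a SurrogateSpec
#' @param nSurrogates number of surrogate pairs.
#' @param seed integer seed.
#' @return A \linkS4class{SurrogateSpec}.
#' @export
surrogateSpec <- function(nSurrogates = 20, seed = 1) {
  new("SurrogateSpec", nSurrogates = as.integer(nSurrogates),
      seed = as.integer(seed))
}
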