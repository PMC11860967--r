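#' Accessors for spike-train objects
#'
#' @param x a \linkS4class{SpikeTrain} or \linkS4class{RecordingSession}.
#' @return \code{spikeTimes}: numeric vector of spike times (s);
#'   \code{nSpikes}: integer spike count; \code{recordingDuration}: window
#'   length (s); \code{electrodeId}, \code{wellId}, \code{timepoint},
#'   \code{conditionLabel}: character labels; \code{trains}: list of
#'   \linkS4class{SpikeTrain}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("electrodeId", function(x) standardGeneric("electrodeId"))
#' @rdname accessors
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))
#' @rdname accessors
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("trains", function(x) standardGeneric("trains"))
#' @rdname accessors
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))

#' @rdname accessors
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
#' @rdname accessors
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))
#' @rdname accessors
setMethod("recordingDuration", "SpikeTrain", function(x) x@duration)
#' @rdname accessors
setMethod("electrodeId", "SpikeTrain", function(x) x@electrodeId)
#' @rdname accessors
setMethod("recordingDuration", "RecordingSession", function(x) x@duration)
#' @rdname accessors
setMethod("wellId", "RecordingSession", function(x) x@wellId)
#' @rdname accessors
setMethod("timepoint", "RecordingSession", function(x) x@timepoint)
#' @rdname accessors
setMethod("conditionLabel", "RecordingSession", function(x) x@label)
#' @rdname accessors
setMethod("trains", "RecordingSession", function(x) x@trains)
#' @rdname accessors
setMethod("sessions", "MEAPlate", function(x) x@sessions)

#' Ground-truth burst annotations of a generated plate
#' @param x an \linkS4class{MEAPlate}.
#' @return data.frame of annotated burst intervals.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname groundTruth
setMethod("groundTruth", "MEAPlate", function(x) x@truth)

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes over %.4g s", object@electrodeId,
              length(object@times), object@duration))
  if (length(object@times))
    cat(sprintf(" (rate %.3g Hz)", length(object@times) / object@duration))
  cat("\n")
})

setMethod("show", "RecordingSession", function(object) {
  cat(sprintf("RecordingSession well '%s' @ '%s' [%s]: %d electrodes, %.4g s\n",
              object@wellId, object@timepoint, object@label,
              length(object@trains), object@duration))
})

setMethod("show", "MEAPlate", function(object) {
  cat(sprintf("MEAPlate: %d sessions (%d wells x %d timepoints), %d electrodes/well\n",
              length(object@sessions), length(object@spec@wells),
              length(object@spec@timepoints), object@spec@electrodesPerWell))
})

setMethod("show", "BurstParams", function(object) {
  cat(sprintf(
    "BurstParams: beginISI<=%.3g s, endISI<=%.3g s, IBI<%.3g s merged, duration>=%.3g s, spikes>=%d\n",
    object@maxBeginIsi, object@maxEndIsi, object@minIbi, object@minDuration,
    object@minSpikes))
})

setMethod("show", "DetectorParams", function(object) {
  cat(sprintf(
    "DetectorParams: threshold %.3g x noise SD, bandpass %.4g-%.4g Hz, fs %.5g Hz, refractory %.3g s\n",
    object@thresholdMultiple, object@bandpassLow, object@bandpassHigh,
    object@fs, object@refractory))
})
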