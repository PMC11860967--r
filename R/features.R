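# Per-electrode spiking/bursting features, electrode inclusion filters and
# per-well aggregation.

.FEATURES <- c("nSpikes", "firingRate", "meanIsi", "burstDuration",
               "burstsPerMin", "spikesInBursts")
# interval-type features are undefined (NA) when no ISI / no burst exists;
# the remaining count-type features are 0 for silent electrodes
.INTERVAL_FEATURES <- c("meanIsi", "burstDuration")

#' Per-electrode spiking and bursting features
#'
#' Computes the six features reported per electrode: spike count, firing
#' rate (Hz), mean interspike interval (s), mean burst duration (s), bursts
#' per minute, and the total number of spikes inside bursts. Interval
#' features that are undefined (fewer than two spikes, or no bursts) are
#' returned as \code{NA}, never silently zero.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param bursts burst data.frame for this train (from
#'   \code{\link{detectBursts}}), or \code{NULL} to detect with defaults.
#' @param params a \linkS4class{BurstParams} used when \code{bursts} is NULL.
#' @return One-row data.frame with columns electrode, the six features, and
#'   \code{nBursts}.
#' @export
electrodeFeatures <- function(train, bursts = NULL, params = burstParams()) {
  stopifnot(is(train, "SpikeTrain"))
  if (is.null(bursts)) bursts <- detectBursts(train, params)
  t <- spikeTimes(train)
  dur <- recordingDuration(train)
  n <- length(t)
  data.frame(
    electrode = electrodeId(train),
    nSpikes = n,
    firingRate = n / dur,
    meanIsi = if (n >= 2L) mean(diff(t)) else NA_real_,
    burstDuration = if (nrow(bursts)) mean(bursts$duration) else NA_real_,
    burstsPerMin = nrow(bursts) / (dur / 60),
    spikesInBursts = sum(bursts$nSpikes),
    nBursts = nrow(bursts))
}

#' Feature table for all electrodes of a session
#'
#' @param session a \linkS4class{RecordingSession}.
#' @param params a \linkS4class{BurstParams}.
#' @return data.frame, one row per electrode.
#' @export
sessionFeatures <- function(session, params = burstParams()) {
  stopifnot(is(session, "RecordingSession"))
  out <- do.call(rbind, lapply(trains(session), electrodeFeatures,
                               params = params))
  if (is.null(out)) out <- electrodeFeatures(spikeTrain(duration = session@duration))[0, ]
  cbind(well = wellId(session), timepoint = timepoint(session),
        label = conditionLabel(session), out)
}

#' Partition electrodes into included / inactive / noisy
#'
#' An electrode is \emph{inactive} when it recorded fewer than
#' \code{minActiveSpikes} spikes in the window, \emph{noisy} when its mean
#' burst duration strictly exceeds \code{noisyMeanBurstDuration} (an
#' electrode at exactly the threshold is retained), and \emph{included}
#' otherwise. The partition is total: every electrode gets exactly one
#' status.
#'
#' @param features per-electrode feature data.frame
#'   (\code{\link{electrodeFeatures}} rows).
#' @param params a \linkS4class{FilterParams}.
#' @return The feature data.frame with an added \code{status} column
#'   (factor: included / inactive / noisy).
#' @export
applyElectrodeFilters <- function(features, params = filterParams()) {
  stopifnot(is(params, "FilterParams"))
  status <- rep("included", nrow(features))
  inactive <- features$nSpikes < params@minActiveSpikes
  noisy <- !inactive & !is.na(features$burstDuration) &
    features$burstDuration > params@noisyMeanBurstDuration + .TIME_EPS
  status[inactive] <- "inactive"
  status[noisy] <- "noisy"
  features$status <- factor(status, levels = c("included", "inactive", "noisy"))
  features
}

#' Aggregate electrode features to a per-well row
#'
#' Takes per-electrode features with filter status and returns the well
#' mean of each feature over included electrodes. Count-type features
#' (spike count, firing rate, bursts/min, spikes in bursts) average over
#' all included electrodes, contributing zeros from silent-but-included
#' electrodes; interval features (mean ISI, burst duration) average only
#' over included electrodes where they are defined. With
#' \code{includeInactive = TRUE}, inactive electrodes additionally
#' contribute zeros to the count-type features (the alternative
#' zero-assignment convention).
#'
#' @param features output of \code{\link{applyElectrodeFilters}} for one
#'   session (must carry well/timepoint/label columns, e.g. from
#'   \code{\link{sessionFeatures}}).
#' @param includeInactive logical; see above (default FALSE).
#' @return One-row data.frame: well, timepoint, label, nActiveElectrodes,
#'   the six well-mean features. If no electrode is included the feature
#'   fields are \code{NA} and a warning is raised.
#' @export
wellFeatures <- function(features, includeInactive = FALSE) {
  stopifnot("status" %in% names(features))
  inc <- features[features$status == "included", , drop = FALSE]
  base <- data.frame(well = features$well[1], timepoint = features$timepoint[1],
                     label = features$label[1],
                     nActiveElectrodes = nrow(inc))
  if (nrow(inc) == 0L && !(includeInactive && any(features$status == "inactive"))) {
    warning(sprintf("well '%s' @ '%s': no included electrodes; features undefined",
                    base$well, base$timepoint))
    for (f in .FEATURES) base[[f]] <- NA_real_
    return(base)
  }
  countPool <- inc
  if (includeInactive) {
    ina <- features[features$status == "inactive", , drop = FALSE]
    if (nrow(ina)) {
      ina[, setdiff(.FEATURES, .INTERVAL_FEATURES)] <- 0
      countPool <- rbind(inc, ina)
    }
  }
  for (f in .FEATURES) {
    base[[f]] <- if (f %in% .INTERVAL_FEATURES) {
      v <- inc[[f]][!is.na(inc[[f]])]
      if (length(v)) mean(v) else NA_real_
    } else mean(countPool[[f]])
  }
  base
}

#' Per-well feature table for a set of sessions
#'
#' Runs burst detection, feature extraction, electrode filtering and
#' per-well aggregation over a list of sessions (or a generated plate).
#'
#' @param x list of \linkS4class{RecordingSession} or an
#'   \linkS4class{MEAPlate}.
#' @param burstP a \linkS4class{BurstParams}.
#' @param filterP a \linkS4class{FilterParams}.
#' @param includeInactive passed to \code{\link{wellFeatures}}.
#' @return list with \code{well} (per-well data.frame) and \code{electrode}
#'   (per-electrode data.frame with filter status, for audit).
#' @export
featureTable <- function(x, burstP = burstParams(), filterP = filterParams(),
                         includeInactive = FALSE) {
  sess <- if (is(x, "MEAPlate")) sessions(x) else x
  elec <- do.call(rbind, lapply(sess, function(s)
    applyElectrodeFilters(sessionFeatures(s, burstP), filterP)))
  wellRows <- do.call(rbind, lapply(split(elec,
      paste(elec$well, elec$timepoint, sep = "\r")),
    wellFeatures, includeInactive = includeInactive))
  rownames(wellRows) <- NULL
  rownames(elec) <- NULL
  list(well = wellRows, electrode = elec)
}
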