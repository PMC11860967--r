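# Spike-timestamp dialects: an open HDF5 layout and a long-format CSV,
# plus tidy CSV output tables.
#
# HDF5 layout: /wells/<well>/<timepoint>/electrodes/<electrode>/timestamps_s
# (1-D float64), with per-timepoint attributes duration_s, label and
# treatment_json.

#' Write recording sessions to the HDF5 spike dialect
#'
#' @param sessions list of \linkS4class{RecordingSession} or an
#'   \linkS4class{MEAPlate}.
#' @param path output file path (overwritten).
#' @return \code{path}, invisibly.
#' @export
writeSpikeH5 <- function(sessions, path) {
  if (is(sessions, "MEAPlate")) sessions <- sessions(sessions)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "wells")
  seen <- character(0)
  for (s in sessions) {
    wgrp <- paste0("wells/", wellId(s))
    if (!wellId(s) %in% seen) {
      rhdf5::h5createGroup(path, wgrp)
      seen <- c(seen, wellId(s))
    }
    tgrp <- paste0(wgrp, "/", timepoint(s))
    rhdf5::h5createGroup(path, tgrp)
    rhdf5::h5createGroup(path, paste0(tgrp, "/electrodes"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, tgrp)
    rhdf5::h5writeAttribute(s@duration, gid, "duration_s")
    rhdf5::h5writeAttribute(conditionLabel(s), gid, "label")
    rhdf5::h5writeAttribute(
      as.character(jsonlite::toJSON(as.list(s@treatment), auto_unbox = TRUE)),
      gid, "treatment_json")
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
    for (tr in trains(s)) {
      egrp <- paste0(tgrp, "/electrodes/", electrodeId(tr))
      rhdf5::h5createGroup(path, egrp)
      rhdf5::h5write(spikeTimes(tr), path, paste0(egrp, "/timestamps_s"))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read recording sessions from the HDF5 spike dialect
#'
#' Validates every train on load (strictly increasing times within the
#' recording window); malformed groups are reported with their HDF5 path.
#'
#' @param path HDF5 file in the layout written by \code{\link{writeSpikeH5}}.
#' @return Named list of \linkS4class{RecordingSession}
#'   (\code{"<well>.<timepoint>"}).
#' @export
readSpikeH5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  wells <- ls$name[ls$group == "/wells"]
  out <- list()
  for (w in sort(wells)) {
    tps <- ls$name[ls$group == paste0("/wells/", w)]
    for (tp in sort(tps)) {
      tgrp <- paste0("/wells/", w, "/", tp)
      attrs <- rhdf5::h5readAttributes(path, tgrp)
      if (is.null(attrs$duration_s))
        stop("missing 'duration_s' attribute at ", tgrp)
      dur <- as.numeric(attrs$duration_s)
      lab <- if (!is.null(attrs$label)) as.character(attrs$label) else "control"
      trt <- if (!is.null(attrs$treatment_json))
        unlist(jsonlite::fromJSON(as.character(attrs$treatment_json)))
      else numeric(0)
      if (is.null(trt)) trt <- numeric(0)
      egrp <- paste0(tgrp, "/electrodes")
      els <- ls$name[ls$group == egrp]
      trs <- lapply(sort(els), function(e) {
        ts <- as.numeric(rhdf5::h5read(path, paste0(egrp, "/", e, "/timestamps_s")))
        if (is.unsorted(ts, strictly = TRUE))
          stop(sprintf("electrode '%s' at %s: times not strictly increasing",
                       e, tgrp))
        spikeTrain(ts, duration = dur, electrodeId = e)
      })
      out[[paste(w, tp, sep = ".")]] <-
        recordingSession(w, tp, trains = trs, label = lab,
                         treatment = trt, duration = dur)
    }
  }
  out
}

#' Write recording sessions to the long-format CSV spike dialect
#'
#' Columns: well, timepoint, label, electrode, time_s, duration_s.
#'
#' @inheritParams writeSpikeH5
#' @return \code{path}, invisibly.
#' @export
writeSpikeCsv <- function(sessions, path) {
  if (is(sessions, "MEAPlate")) sessions <- sessions(sessions)
  rows <- lapply(sessions, function(s) {
    do.call(rbind, lapply(trains(s), function(tr) {
      if (!nSpikes(tr)) return(NULL)
      data.frame(well = wellId(s), timepoint = timepoint(s),
                 label = conditionLabel(s), electrode = electrodeId(tr),
                 time_s = spikeTimes(tr), duration_s = s@duration)
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(well = character(0), timepoint = character(0),
                     label = character(0), electrode = character(0),
                     time_s = numeric(0), duration_s = numeric(0))
  # full float64 precision so CSV and HDF5 encodings load identically
  df$time_s <- sprintf("%.17g", df$time_s)
  df$duration_s <- sprintf("%.17g", df$duration_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read recording sessions from the long-format CSV spike dialect
#'
#' Requires columns well, timepoint, electrode, time_s; optional label and
#' duration_s (otherwise \code{duration} is used). Times are sorted on
#' load with a warning when reordering was needed.
#'
#' @param path CSV file path.
#' @param duration fallback recording duration in seconds when the file
#'   has no duration_s column (default 1800).
#' @return Named list of \linkS4class{RecordingSession}.
#' @export
readSpikeCsv <- function(path, duration = 1800) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "timepoint", "electrode", "time_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing required column(s) %s; found: %s",
                 paste(miss, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  if (!nrow(df)) return(list())
  out <- list()
  for (key in unique(paste(df$well, df$timepoint, sep = "."))) {
    sub <- df[paste(df$well, df$timepoint, sep = ".") == key, , drop = FALSE]
    dur <- if ("duration_s" %in% names(sub)) sub$duration_s[1] else duration
    lab <- if ("label" %in% names(sub)) sub$label[1] else "control"
    trs <- lapply(sort(unique(sub$electrode)), function(e) {
      ts <- sub$time_s[sub$electrode == e]
      spikeTrain(ts, duration = dur, electrodeId = e, sort = TRUE)
    })
    out[[key]] <- recordingSession(sub$well[1], sub$timepoint[1],
                                   trains = trs, label = lab, duration = dur)
  }
  out
}

#' Write a tidy feature (or fold-change) table to CSV
#'
#' One row per well and timepoint, stable column order, undefined values
#' encoded as empty fields (not "NA" text).
#'
#' @param rows data.frame of per-well rows.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tidy feature table written by \code{\link{writeFeatureTable}}
#' @param path CSV path.
#' @return data.frame with empty fields decoded as \code{NA}.
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
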