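# End-to-end analysis: baseline normalization, fold change against
# age-matched control wells, repeated-measures group statistics, and the
# orchestrating runPipeline().

#' Feature names used throughout the pipeline
#' @return Character vector of the six per-well feature names.
#' @export
featureNames <- function() .FEATURES

.toLong <- function(wellDf) {
  out <- do.call(rbind, lapply(.FEATURES, function(f)
    data.frame(well = wellDf$well, timepoint = wellDf$timepoint,
               label = wellDf$label, feature = f, value = wellDf[[f]])))
  rownames(out) <- NULL
  out
}

#' Normalize well features to their own baseline
#'
#' Divides each well's post-exposure feature value by that well's value at
#' the baseline timepoint (pre-exposure), feature by feature, which
#' removes well-to-well offsets and pipetting disturbances. Wells with a
#' zero or undefined baseline are flagged and their normalized values set
#' to \code{NA} (excluded from downstream ratios).
#'
#' @param wellDf per-well feature data.frame (from
#'   \code{\link{featureTable}$well}).
#' @param baselineTimepoint label of the pre-exposure timepoint
#'   (default "baseline").
#' @return Long data.frame: well, timepoint, label, feature,
#'   baselineValue, value, baselineNormalized (baseline rows excluded).
#' @export
baselineNormalize <- function(wellDf, baselineTimepoint = "baseline") {
  long <- .toLong(wellDf)
  base <- long[long$timepoint == baselineTimepoint, c("well", "feature", "value")]
  names(base)[3] <- "baselineValue"
  missingWells <- setdiff(unique(long$well), unique(base$well))
  if (length(missingWells))
    stop("no baseline timepoint for well(s): ",
         paste(missingWells, collapse = ", "))
  post <- long[long$timepoint != baselineTimepoint, , drop = FALSE]
  out <- merge(post, base, by = c("well", "feature"), sort = FALSE)
  bad <- is.na(out$baselineValue) | out$baselineValue <= 0
  out$baselineNormalized <- ifelse(bad, NA_real_,
                                   out$value / out$baselineValue)
  out$baselineFlagged <- bad
  out
}

#' Fold change relative to age-matched control wells
#'
#' Each treated well's baseline-normalized value is divided by the mean of
#' the control wells' baseline-normalized values at the same timepoint
#' (the age-matched comparison). Control wells' own fold changes average
#' to 1 at every timepoint by construction.
#'
#' @param normDf output of \code{\link{baselineNormalize}}.
#' @param controlLabel condition label of the control wells
#'   (default "control").
#' @return The input with added columns controlMean and foldChange.
#'   Rows where the control mean is undefined or non-positive are dropped
#'   with a message.
#' @export
controlFoldChange <- function(normDf, controlLabel = "control") {
  if (!any(normDf$label == controlLabel))
    stop("no wells with control label '", controlLabel, "'")
  key <- paste(normDf$timepoint, normDf$feature, sep = "\r")
  ctrl <- normDf$label == controlLabel
  for (k in unique(key)) {
    if (!any(ctrl & key == k & !is.na(normDf$baselineNormalized))) {
      parts <- strsplit(k, "\r")[[1]]
      stop(sprintf("no control wells with defined values at timepoint '%s' (feature %s)",
                   parts[1], parts[2]))
    }
  }
  cm <- tapply(normDf$baselineNormalized[ctrl], key[ctrl], mean, na.rm = TRUE)
  normDf$controlMean <- as.numeric(cm[key])
  undef <- is.na(normDf$controlMean) | normDf$controlMean <= 0
  normDf$foldChange <- ifelse(undef, NA_real_,
                              normDf$baselineNormalized / normDf$controlMean)
  if (any(undef & !is.na(normDf$baselineNormalized)))
    message(sum(undef), " rows dropped: undefined control-mean denominator")
  normDf
}

#' Repeated-measures group statistics on fold changes
#'
#' For each feature, fits a mixed-effects repeated-measures model of the
#' fold change with fixed effects condition, timepoint and their
#' interaction and a random intercept per well
#' (\code{lmerTest::lmer(foldChange ~ label * timepoint + (1 | well))}),
#' then runs control-referenced comparisons at each timepoint
#' (\code{emmeans} treatment-vs-control contrasts) with Dunnett-style
#' familywise adjustment. The significance threshold is recorded in the
#' output.
#'
#' @param fc fold-change table from \code{\link{controlFoldChange}}.
#' @param controlLabel control condition label.
#' @param alpha significance threshold (default 0.05).
#' @return list with \code{anova} (per-feature factor effects) and
#'   \code{contrasts} (per feature/timepoint/condition comparison vs
#'   control with adjusted p-values and a \code{significant} flag), plus
#'   \code{alpha}.
#' @export
groupStats <- function(fc, controlLabel = "control", alpha = 0.05) {
  fc <- fc[!is.na(fc$foldChange), , drop = FALSE]
  labs <- unique(fc$label)
  if (length(labs) < 2L)
    stop("singular design: need at least two conditions")
  if (length(unique(fc$timepoint)) < 2L)
    stop("singular design: need repeated timepoints")
  perCond <- tapply(fc$well, fc$label, function(w) length(unique(w)))
  if (any(perCond < 2L))
    stop("singular design: need >= 2 wells per condition")
  anovaRows <- list(); contrastRows <- list()
  for (f in unique(fc$feature)) {
    d <- fc[fc$feature == f, , drop = FALSE]
    d$label <- stats::relevel(factor(d$label), ref = controlLabel)
    d$timepoint <- factor(d$timepoint, levels = unique(fc$timepoint))
    m <- suppressMessages(suppressWarnings(
      lmerTest::lmer(foldChange ~ label * timepoint + (1 | well), data = d)))
    a <- as.data.frame(stats::anova(m))
    anovaRows[[f]] <- cbind(feature = f, effect = rownames(a), a,
                            row.names = NULL)
    emm <- suppressMessages(
      emmeans::emmeans(m, ~ label | timepoint, lmer.df = "satterthwaite"))
    ct <- as.data.frame(summary(
      emmeans::contrast(emm, method = "trt.vs.ctrl", ref = 1,
                        adjust = "dunnettx")))
    ct$significant <- ct$p.value < alpha
    contrastRows[[f]] <- cbind(feature = f, ct, row.names = NULL)
  }
  list(anova = do.call(rbind, anovaRows),
       contrasts = do.call(rbind, contrastRows),
       alpha = alpha)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study analysis end to end: obtain sessions (simulate a
#' plate or read a spike file), detect bursts and extract per-electrode
#' and per-well features, optionally score pairwise synchrony, normalize
#' to baseline and to age-matched controls, and (optionally) run group
#' statistics. All intermediates are written as tidy CSVs together with a
#' JSON manifest recording parameters and seeds; reruns with the same
#' configuration are identical.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{simulate}{list with \code{nPerArm}, \code{electrodesPerWell},
#'       \code{masterSeed}, optional \code{timepoints}, \code{gen} (TrainGenSpec
#'       fields) and \code{effect} (TreatmentEffect fields); or}
#'     \item{input}{list with \code{path} and \code{format} ("h5" or "csv")}
#'     \item{analysis}{optional overrides: \code{baselineTimepoint},
#'       \code{controlLabel}, \code{includeInactive}, \code{burst} (BurstParams
#'       fields), \code{filter} (FilterParams fields), \code{synchrony}
#'       (\code{enabled}, \code{nSurrogates}, \code{seed}), \code{stats}
#'       (\code{enabled}, \code{alpha})}
#'     \item{outputDir}{directory for result files (created)}
#'   }
#' @return Invisibly, a list with wellFeatures, electrodeFeatures,
#'   foldChange, synchrony (or NULL), stats (or NULL), and the manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outDir <- config$outputDir
  if (is.null(outDir)) stop("config$outputDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "pipeline.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logFile, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  an <- config$analysis
  burstP <- do.call(burstParams, as.list(an$burst))
  filterP <- do.call(filterParams, as.list(an$filter))
  baselineTp <- if (is.null(an$baselineTimepoint)) "baseline" else an$baselineTimepoint
  controlLab <- if (is.null(an$controlLabel)) "control" else an$controlLabel

  plate <- NULL
  sess <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      gen <- do.call(trainGenSpec, as.list(sim$gen))
      eff <- do.call(treatmentEffect, as.list(sim$effect))
      args <- list(gen = gen, effect = eff)
      if (!is.null(sim$nPerArm)) args$nPerArm <- sim$nPerArm
      if (!is.null(sim$electrodesPerWell)) args$electrodesPerWell <- sim$electrodesPerWell
      if (!is.null(sim$timepoints)) args$timepoints <- sim$timepoints
      if (!is.null(sim$masterSeed)) args$masterSeed <- sim$masterSeed
      plate <- generatePlate(do.call(twoArmPlateSpec, args))
      sessions(plate)
    } else if (!is.null(config$input)) {
      if (identical(config$input$format, "csv"))
        readSpikeCsv(config$input$path)
      else readSpikeH5(config$input$path)
    } else stop("config needs either 'simulate' or 'input'")
  })
  logmsg("input: %d sessions", length(sess))

  ft <- stage("features", featureTable(
    sess, burstP = burstP, filterP = filterP,
    includeInactive = isTRUE(an$includeInactive)))
  writeFeatureTable(ft$well, file.path(outDir, "well_features.csv"))
  writeFeatureTable(ft$electrode, file.path(outDir, "electrode_features.csv"))

  syn <- NULL
  if (isTRUE(an$synchrony$enabled)) {
    syn <- stage("synchrony", {
      sspec <- surrogateSpec(
        nSurrogates = if (is.null(an$synchrony$nSurrogates)) 20 else an$synchrony$nSurrogates,
        seed = if (is.null(an$synchrony$seed)) 1 else an$synchrony$seed)
      res <- lapply(sess, function(s) {
        elec <- ft$electrode[ft$electrode$well == wellId(s) &
                               ft$electrode$timepoint == timepoint(s), ]
        wellSynchrony(s, elec, sspec)
      })
      pairs <- do.call(rbind, lapply(res, `[[`, "pairs"))
      summ <- data.frame(
        well = vapply(sess, wellId, ""),
        timepoint = vapply(sess, timepoint, ""),
        meanSynchrony = vapply(res, `[[`, 0, "mean"))
      writeFeatureTable(pairs, file.path(outDir, "synchrony_pairs.csv"))
      writeFeatureTable(summ, file.path(outDir, "synchrony_summary.csv"))
      list(pairs = pairs, summary = summ)
    })
  }

  fcTab <- stage("foldchange", {
    norm <- baselineNormalize(ft$well, baselineTimepoint = baselineTp)
    controlFoldChange(norm, controlLabel = controlLab)
  })
  writeFeatureTable(fcTab, file.path(outDir, "fold_change.csv"))

  st <- NULL
  if (!identical(an$stats$enabled, FALSE)) {
    st <- stage("stats", groupStats(
      fcTab, controlLabel = controlLab,
      alpha = if (is.null(an$stats$alpha)) 0.05 else an$stats$alpha))
    writeFeatureTable(st$anova, file.path(outDir, "stats_anova.csv"))
    writeFeatureTable(st$contrasts, file.path(outDir, "stats_contrasts.csv"))
  }

  manifest <- list(
    package = "meapipe",
    version = as.character(utils::packageVersion("meapipe")),
    config = config,
    burstParams = list(maxBeginIsi = burstP@maxBeginIsi,
                       maxEndIsi = burstP@maxEndIsi, minIbi = burstP@minIbi,
                       minDuration = burstP@minDuration,
                       minSpikes = burstP@minSpikes),
    filterParams = list(minActiveSpikes = filterP@minActiveSpikes,
                        noisyMeanBurstDuration = filterP@noisyMeanBurstDuration))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logmsg("pipeline complete")
  invisible(list(wellFeatures = ft$well, electrodeFeatures = ft$electrode,
                 foldChange = fcTab, synchrony = syn, stats = st,
                 plate = plate, manifest = manifest))
}
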