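# Black-box recovery of the pipeline's decision constants by boundary
# search on synthetic inputs. Each sweep treats the corresponding stage as
# an opaque function and locates the input at which its decision flips, so
# the recovered values certify the implemented thresholds end to end.

#' Recover the pipeline's decision constants by boundary search
#'
#' Sweeps synthetic inputs across each decision boundary of the spike
#' detector, the max-interval burst detector and the electrode filters,
#' and reports the constant each stage actually implements:
#' \describe{
#'   \item{thresholdMultiple}{smallest spike amplitude (in multiples of
#'     the noise SD, 0.1 grid) at which all template spikes injected on a
#'     flat trace are detected; the SD is estimated from a separate 60-s
#'     noise-only calibration trace.}
#'   \item{singleBurstMaxIsi}{largest uniform interspike interval (1-ms
#'     grid) at which a 10-spike train is reported as a single burst
#'     containing all 10 spikes.}
#'   \item{burstExtensionIsi}{largest trailing gap (10-ms grid) at which a
#'     spike appended after an 8-spike burst is still assigned to it.}
#'   \item{burstSeparationGap}{smallest gap between two 6-spike clusters
#'     (10-ms grid) reported as two bursts rather than one.}
#'   \item{minBurstDuration}{smallest total duration of an accepted
#'     6-spike burst (uniform-ISI trains on a 1-ms grid).}
#'   \item{minBurstSpikes}{smallest cluster size (50-ms ISIs) reported as
#'     a burst, k swept over 1..12.}
#'   \item{minActiveSpikes}{smallest spike count in a 30-min recording
#'     classified as an included (active) electrode, k swept over 1..20.}
#'   \item{noisyDurationLimit}{largest mean burst duration (10-ms grid,
#'     4--6 s) not excluded as noisy.}
#' }
#'
#' @param detectorP a \linkS4class{DetectorParams}.
#' @param burstP a \linkS4class{BurstParams}.
#' @param filterP a \linkS4class{FilterParams}.
#' @param seed seed for the calibration noise trace.
#' @return Named list of the eight recovered constants.
#' @export
recoverPipelineConstants <- function(detectorP = detectorParams(),
                                     burstP = burstParams(),
                                     filterP = filterParams(),
                                     seed = 1) {
  fs <- detectorP@fs

  ## spike threshold: sigma from a separate noise-only calibration trace,
  ## then template spikes of amplitude a * sigma on an otherwise flat trace
  calib <- withSeed(hashSeed(seed, "calibration"),
                    stats::rnorm(60 * fs, 0, 1))
  sigma <- estimateNoiseSd(calib, fs = fs)
  spikeAt <- seq(1, 58, length.out = 20)
  flat <- numeric(60 * fs)
  thresholdMultiple <- NA_real_
  for (a in (10:100) / 10) {
    tr <- injectSpikes(flat, spikeAt, a * sigma, fs = fs)
    if (nSpikes(detectSpikes(tr, detectorP, noiseSd = sigma)) ==
        length(spikeAt)) { thresholdMultiple <- a; break }
  }

  ## largest uniform ISI keeping 10 equally spaced spikes one burst
  singleBurstMaxIsi <- NA_real_
  for (g in (1:300) / 1000) {
    b <- detectBursts(spikeTrain((0:9) * g, duration = 1800), burstP)
    if (nrow(b) == 1L && b$nSpikes == 10L) singleBurstMaxIsi <- g
  }

  ## largest trailing gap still absorbed into an established burst
  burstExtensionIsi <- NA_real_
  core <- (0:7) * 0.05
  for (g in (1:60) / 100) {
    b <- detectBursts(spikeTrain(c(core, core[8] + g), duration = 1800),
                      burstP)
    if (nrow(b) == 1L && b$nSpikes == 9L) burstExtensionIsi <- g
  }

  ## smallest gap splitting two 6-spike clusters into two bursts
  burstSeparationGap <- NA_real_
  c1 <- (0:5) * 0.05
  for (g in (25:100) / 100) {
    b <- detectBursts(spikeTrain(c(c1, c1[6] + g + c1), duration = 1800),
                      burstP)
    if (nrow(b) == 2L) { burstSeparationGap <- g; break }
  }

  ## smallest accepted total burst duration (6 spikes, uniform ISI)
  minBurstDuration <- NA_real_
  for (g in (1:50) / 1000) {
    b <- detectBursts(spikeTrain((0:5) * g, duration = 1800), burstP)
    if (nrow(b) == 1L) { minBurstDuration <- 5 * g; break }
  }

  ## smallest spike count reported as a burst
  minBurstSpikes <- NA_integer_
  for (k in 1:12) {
    b <- detectBursts(spikeTrain((seq_len(k) - 1) * 0.05, duration = 1800),
                      burstP)
    if (nrow(b) == 1L) { minBurstSpikes <- k; break }
  }

  ## smallest spike count classified as an included electrode
  minActiveSpikes <- NA_integer_
  for (k in 1:20) {
    st <- spikeTrain(seq_len(k) * 60, duration = 1800)
    f <- applyElectrodeFilters(electrodeFeatures(st, params = burstP),
                               filterP)
    if (f$status == "included") { minActiveSpikes <- k; break }
  }

  ## largest mean burst duration retained (not flagged noisy); electrodes
  ## carry a single long uniform-ISI burst of duration d
  noisyDurationLimit <- NA_real_
  for (d in (400:600) / 100) {
    n <- 100L
    st <- spikeTrain((0:n) * (d / n), duration = 1800)
    f <- applyElectrodeFilters(electrodeFeatures(st, params = burstP),
                               filterP)
    if (f$status == "included") noisyDurationLimit <- d
  }

  list(thresholdMultiple = thresholdMultiple,
       singleBurstMaxIsi = singleBurstMaxIsi,
       burstExtensionIsi = burstExtensionIsi,
       burstSeparationGap = burstSeparationGap,
       minBurstDuration = minBurstDuration,
       minBurstSpikes = minBurstSpikes,
       minActiveSpikes = minActiveSpikes,
       noisyDurationLimit = noisyDurationLimit)
}
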