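test_that("electrode features follow their defining arithmetic", {
  # 10 spikes, no bursts
  st <- spikeTrain(seq_len(10) * 60, duration = 1800)
  f <- electrodeFeatures(st)
  expect_equal(f$firingRate, 10 / 1800)
  expect_identical(f$spikesInBursts, 0L)
  expect_true(is.na(f$burstDuration))
  expect_equal(f$meanIsi, 60)

  # the worked single-burst train
  st2 <- spikeTrain(seq(0, 0.25, by = 0.05), duration = 1800)
  f2 <- electrodeFeatures(st2)
  expect_equal(f2$burstDuration, 0.25)
  expect_identical(f2$spikesInBursts, 6L)
  expect_equal(f2$burstsPerMin, 1 / 30)

  # empty train: counts zero, interval features flagged undefined
  f3 <- electrodeFeatures(spikeTrain(numeric(0), duration = 1800))
  expect_identical(f3$nSpikes, 0L)
  expect_equal(f3$firingRate, 0)
  expect_true(is.na(f3$meanIsi))
  expect_true(is.na(f3$burstDuration))
})

test_that("electrode filter partitions by activity and burst-duration rules", {
  mk <- function(nSpikes, burstDuration) {
    data.frame(electrode = "e", nSpikes = nSpikes, firingRate = nSpikes / 1800,
               meanIsi = 1, burstDuration = burstDuration, burstsPerMin = 1,
               spikesInBursts = 0L, nBursts = 1L)
  }
  f <- applyElectrodeFilters(rbind(mk(9, 0.2), mk(10, 0.2), mk(100, 5.0),
                                   mk(100, 6.1), mk(11, NA)))
  expect_identical(as.character(f$status),
                   c("inactive", "included", "included", "noisy", "included"))
  # partition is total: exactly one status each
  expect_false(anyNA(f$status))
})

test_that("well means pool included electrodes under the stated conventions", {
  mkRow <- function(el, nSpikes, firingRate, meanIsi, burstDuration, status) {
    data.frame(well = "w1", timepoint = "30m", label = "control",
               electrode = el, nSpikes = nSpikes, firingRate = firingRate,
               meanIsi = meanIsi, burstDuration = burstDuration,
               burstsPerMin = 1, spikesInBursts = 10L, nBursts = 1L,
               status = factor(status,
                               levels = c("included", "inactive", "noisy")))
  }
  two <- rbind(mkRow("e1", 1800L, 1, 1, 0.2, "included"),
               mkRow("e2", 5400L, 3, 1 / 3, 0.3, "included"))
  w <- wellFeatures(two)
  expect_equal(w$firingRate, 2)
  expect_identical(w$nActiveElectrodes, 2L)

  # interval features average only where defined
  mixed <- rbind(mkRow("e1", 1800L, 1, 1, 0.2, "included"),
                 mkRow("e2", 1800L, 1, 1, NA, "included"))
  expect_equal(wellFeatures(mixed)$burstDuration, 0.2)

  # all electrodes inactive: undefined row with a warning
  allIn <- rbind(mkRow("e1", 3L, 0.01, 1, NA, "inactive"),
                 mkRow("e2", 5L, 0.01, 1, NA, "inactive"))
  expect_warning(w0 <- wellFeatures(allIn), "no included")
  expect_true(is.na(w0$firingRate))
  expect_identical(w0$nActiveElectrodes, 0L)

  # permutation invariance in electrode order
  expect_equal(wellFeatures(two[2:1, ])[, -(1:3)], w[, -(1:3)])
})

test_that("well features recover generator ground truth within sampling error", {
  spec <- trainGenSpec(backgroundRate = 0.1, burstRate = 6,
                       spikesPerBurstMean = 8, intraBurstIsi = 0.02,
                       duration = 1800)
  conds <- list(w1 = list(gen = spec, label = "control"))
  for (seed in 1:3) {
    pl <- generatePlate(plateSpec(conds, electrodesPerWell = 12,
                                  timepoints = "baseline", masterSeed = seed))
    ann <- groundTruth(pl)
    # annotation-derived per-plate means against generator intent
    expect_lt(abs(mean(ann$nSpikes) - 8) / 8, 0.1)
    burstsPerMinTrue <- nrow(ann) / 12 / 30
    expect_lt(abs(burstsPerMinTrue - 6) / 6, 0.1)
  }
})
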