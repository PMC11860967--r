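test_that("Poisson generator matches its closed-form distribution", {
  expect_identical(nSpikes(generatePoissonTrain(0, 1800, seed = 1)), 0L)

  tr <- generatePoissonTrain(2, 1800, seed = 42)
  n <- nSpikes(tr)
  ci <- qpois(c(5e-4, 1 - 5e-4), 2 * 1800)
  expect_gte(n, ci[1]); expect_lte(n, ci[2])
  # interspike intervals of a Poisson process are exponential(rate)
  ks <- suppressWarnings(ks.test(diff(spikeTimes(tr)), "pexp", 2))
  expect_gt(ks$p.value, 0.001)

  expect_identical(spikeTimes(generatePoissonTrain(2, 100, seed = 7)),
                   spikeTimes(generatePoissonTrain(2, 100, seed = 7)))
})

test_that("Poisson counts have the right mean and variance across seeds", {
  counts <- vapply(1:200, function(s)
    nSpikes(generatePoissonTrain(2, 1800, seed = s)), 0L)
  expect_lt(abs(mean(counts) - 3600) / 3600, 0.01)
  expect_lt(abs(var(counts) - 3600) / 3600, 0.10)
})

test_that("generated trains are sorted, deduplicated and inside the window", {
  for (s in 1:20) {
    tr <- generateBurstingTrain(trainGenSpec(duration = 120), seed = s)
    t <- spikeTimes(tr)
    expect_false(is.unsorted(t, strictly = TRUE))
    if (length(t)) {
      expect_gte(t[1], 0)
      expect_lt(t[length(t)], 120)
    }
  }
})

test_that("bursting generator degenerates to the Poisson generator", {
  spec <- trainGenSpec(backgroundRate = 1, burstRate = 0, duration = 300)
  a <- generateBurstingTrain(spec, seed = 9)
  b <- generatePoissonTrain(1, 300, seed = 9)
  expect_identical(spikeTimes(a), spikeTimes(b))
  expect_identical(nrow(attr(a, "annotations")), 0L)
})

test_that("ground-truth annotations reflect the generator parameters", {
  spec <- trainGenSpec(backgroundRate = 0.05, burstRate = 4,
                       spikesPerBurstMean = 8, intraBurstIsi = 0.02,
                       duration = 1800)
  ann <- do.call(rbind, lapply(1:3, function(s)
    attr(generateBurstingTrain(spec, seed = s), "annotations")))
  clean <- ann[!ann$truncated, ]
  # annotated duration is (n-1)*isi for unmerged episodes, which dominate
  # at this burst rate (merged intervals deviate in either direction)
  gap <- (clean$offset - clean$onset) - (clean$nSpikes - 1) * 0.02
  expect_gt(mean(abs(gap) < 1e-9), 0.95)
  expect_lt(abs(mean(clean$nSpikes) - 8) / 8, 0.1)

  # halving the spikes-per-burst mean halves the annotated mean
  half <- applyEffect(spec, treatmentEffect(spikesPerBurstScale = 0.5))
  annH <- do.call(rbind, lapply(1:3, function(s)
    attr(generateBurstingTrain(half, seed = s + 100), "annotations")))
  expect_lt(abs(mean(annH$nSpikes) / mean(clean$nSpikes) - 0.5), 0.1)
})

test_that("applyEffect scales the intended generator fields and nothing else", {
  spec <- trainGenSpec(backgroundRate = 2, burstRate = 10,
                       spikesPerBurstMean = 8, intraBurstIsi = 0.02)
  expect_equal(applyEffect(spec, treatmentEffect()), spec)
  e <- applyEffect(spec, treatmentEffect(firingRateScale = 0.5))
  expect_equal(e@backgroundRate, 1)
  expect_equal(e@burstRate, spec@burstRate)
  e <- applyEffect(spec, treatmentEffect(burstDurationScale = 0.5))
  expect_equal(e@intraBurstIsi, 0.01)
  expect_equal(e@spikesPerBurstMean, spec@spikesPerBurstMean)
})

test_that("generatePlate produces one session per well and timepoint, reproducibly", {
  ps <- twoArmPlateSpec(gen = trainGenSpec(duration = 60), nPerArm = 3,
                        electrodesPerWell = 4,
                        timepoints = c("baseline", "30m", "1D"),
                        masterSeed = 11)
  pl <- generatePlate(ps)
  expect_length(sessions(pl), 6 * 3)
  expect_true(all(vapply(sessions(pl), function(s) length(trains(s)), 0L) == 4L))
  pl2 <- generatePlate(ps)
  expect_identical(
    lapply(sessions(pl), function(s) lapply(trains(s), spikeTimes)),
    lapply(sessions(pl2), function(s) lapply(trains(s), spikeTimes)))
})

test_that("control wells show no systematic drift across timepoints", {
  ps <- twoArmPlateSpec(gen = trainGenSpec(), nPerArm = 1,
                        electrodesPerWell = 16,
                        timepoints = c("baseline", "7D"), masterSeed = 3)
  pl <- generatePlate(ps)
  ss <- sessions(pl)
  rate <- function(s) mean(vapply(trains(s), function(tr)
    nSpikes(tr) / recordingDuration(tr), 0))
  r0 <- rate(ss[["C01.baseline"]]); r1 <- rate(ss[["C01.7D"]])
  expect_lt(abs(r1 - r0) / r0, 0.1)  # sampling noise only
})

test_that("correlated-pair harness jitters, thins and clips as configured", {
  base <- generatePoissonTrain(2, 100, seed = 5)
  p0 <- generateCorrelatedPair(base, 0, 0, seed = 1)
  expect_identical(spikeTimes(p0$a), spikeTimes(p0$b))
  pThin <- generateCorrelatedPair(base, 0, 0.5, seed = 2)
  nb <- nSpikes(pThin$b)
  expect_gt(nb, qbinom(5e-4, nSpikes(base), 0.5))
  expect_lt(nb, qbinom(1 - 5e-4, nSpikes(base), 0.5))
  pJit <- generateCorrelatedPair(base, 0.02, 0, seed = 3)
  t <- spikeTimes(pJit$b)
  expect_false(is.unsorted(t, strictly = TRUE))
  expect_true(all(t >= 0 & t < 100))
})

test_that("raw traces carry calibrated noise and reproducible spike waveforms", {
  empty <- spikeTrain(numeric(0), duration = 60)
  tr <- generateRawTrace(empty, noiseSd = 1, fs = 10000, seed = 8)
  expect_length(tr, 60 * 10000)
  expect_lt(abs(sd(tr) - 1), 0.02)
  # zero amplitude leaves the noise untouched for the same seed
  st <- spikeTrain(c(1, 2, 3), duration = 60)
  tr0 <- generateRawTrace(st, spikeAmplitude = 0, noiseSd = 1, fs = 10000,
                          seed = 8)
  expect_identical(tr0, tr)
  # template negative peak is exactly -1 before scaling
  expect_identical(min(spikeTemplate(10000)), -1)
})
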