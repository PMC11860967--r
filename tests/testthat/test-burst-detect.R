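test_that("default burst parameters are the standard max-interval settings", {
  p <- burstParams()
  expect_equal(c(p@maxBeginIsi, p@maxEndIsi, p@minIbi, p@minDuration),
               c(0.1, 0.2, 0.5, 0.05))
  expect_identical(p@minSpikes, 6L)
})

test_that("scan finds maximal disjoint candidates per the start/extend rules", {
  st <- spikeTrain(seq(0, 0.25, by = 0.05), duration = 10)
  cand <- scanBursts(st)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$firstIndex, 1L)
  expect_identical(cand$lastIndex, 6L)
  expect_equal(cand$duration, 0.25)

  expect_identical(nrow(scanBursts(spikeTrain(numeric(0), duration = 10))), 0L)
  expect_identical(nrow(scanBursts(spikeTrain(1, duration = 10))), 0L)
  # all ISIs 0.15 > begin threshold: nothing can start
  expect_identical(nrow(scanBursts(spikeTrain(c(0, 0.15, 0.30),
                                              duration = 10))), 0L)
})

test_that("candidates separated by less than the minimum IBI are merged", {
  p <- burstParams()
  mkTrain <- function(gap) {
    c1 <- (0:5) * 0.05
    spikeTrain(c(c1, 0.25 + gap + c1), duration = 10)
  }
  tr <- mkTrain(0.3)
  merged <- mergeBursts(scanBursts(tr, p), p, tr)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$nSpikes, 12L)

  # gap exactly at the minimum IBI: not merged (strict <)
  tr5 <- mkTrain(0.5)
  merged5 <- mergeBursts(scanBursts(tr5, p), p, tr5)
  expect_identical(nrow(merged5), 2L)

  single <- scanBursts(mkTrain(5), p)[1, ]
  expect_identical(mergeBursts(single, p, mkTrain(5)), single)
})

test_that("duration and spike-count filters apply inclusively", {
  p <- burstParams()
  keep <- detectBursts(spikeTrain((0:5) * 0.05, duration = 10), p)
  expect_identical(nrow(keep), 1L)
  # 5 spikes over 0.2 s: too few spikes
  expect_identical(nrow(detectBursts(spikeTrain((0:4) * 0.05, duration = 10),
                                     p)), 0L)
  # 6 spikes over 0.045 s: too short
  expect_identical(nrow(detectBursts(spikeTrain((0:5) * 0.009, duration = 10),
                                     p)), 0L)
})

test_that("boundary sweeps recover the configured burst constants", {
  # smallest cluster size reported as a burst
  firstK <- NA
  for (k in 1:12) {
    if (nrow(detectBursts(spikeTrain((seq_len(k) - 1) * 0.05,
                                     duration = 10)))) { firstK <- k; break }
  }
  expect_identical(firstK, 6L)
  # largest uniform ISI keeping a 10-spike train a single burst
  ok <- vapply((1:300) / 1000, function(g) {
    b <- detectBursts(spikeTrain((0:9) * g, duration = 10))
    nrow(b) == 1L && b$nSpikes == 10L
  }, TRUE)
  expect_equal(max(((1:300) / 1000)[ok]), 0.1)
})

test_that("detector equals the exhaustive oracle on random trains", {
  set.seed(101)
  p <- burstParams()
  for (i in 1:200) {
    t <- randomTestTrain()
    got <- detectBursts(spikeTrain(t, duration = max(t) + 1), p)
    want <- bruteForceBursts(t)
    expect_identical(got$firstIndex, want$firstIndex)
    expect_identical(got$lastIndex, want$lastIndex)
  }
})

test_that("adding a spike inside a burst never removes the burst", {
  set.seed(202)
  checked <- 0
  for (i in 1:200) {
    t <- randomTestTrain()
    st <- spikeTrain(t, duration = max(t) + 1)
    b <- detectBursts(st)
    if (!nrow(b)) next
    k <- sample(nrow(b), 1)
    i0 <- b$firstIndex[k]
    mid <- (t[i0] + t[i0 + 1]) / 2
    if (any(abs(t - mid) < 1e-12)) next
    b2 <- detectBursts(spikeTrain(sort(c(t, mid)), duration = max(t) + 1))
    expect_true(any(b2$onset <= b$onset[k] + 1e-12 &
                    b2$offset >= b$offset[k] - 1e-12))
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("every reported burst satisfies the duration and count thresholds", {
  set.seed(303)
  p <- burstParams()
  for (i in 1:100) {
    t <- randomTestTrain()
    b <- detectBursts(spikeTrain(t, duration = max(t) + 1), p)
    if (!nrow(b)) next
    expect_true(all(b$duration >= p@minDuration - 1e-9))
    expect_true(all(b$nSpikes >= p@minSpikes))
    # disjoint and ordered
    if (nrow(b) > 1)
      expect_true(all(b$onset[-1] > b$offset[-nrow(b)]))
  }
})
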