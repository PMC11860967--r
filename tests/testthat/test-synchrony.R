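test_that("spike distance is zero for identical trains and symmetric", {
  set.seed(7)
  for (i in 1:5) {
    a <- sort(runif(sample(3:50, 1), 0, 10))
    expect_identical(spikeDistance(a, a, duration = 10), 0)
  }
  for (i in 1:100) {
    a <- sort(runif(sample(2:40, 1), 0, 10))
    b <- sort(runif(sample(2:40, 1), 0, 10))
    expect_identical(spikeDistance(a, b, duration = 10),
                     spikeDistance(b, a, duration = 10))
  }
})

test_that("piecewise integration matches the dense-grid oracle", {
  a <- seq(0.5, 99.5, by = 1)
  b <- seq(1.0, 99.5, by = 1)  # antiphase periodic pair
  expect_lt(abs(spikeDistance(a, b, duration = 100) -
                gridSpikeDistance(a, b, 100)), 1e-3)
  set.seed(11)
  for (i in 1:10) {
    ra <- runif(1, 0.5, 8); rb <- runif(1, 0.5, 8)
    x <- sort(runif(rpois(1, ra * 50), 0, 50))
    y <- sort(runif(rpois(1, rb * 50), 0, 50))
    expect_lt(abs(spikeDistance(x, y, duration = 50) -
                  gridSpikeDistance(x, y, 50)), 1e-3)
  }
})

test_that("spike distance is invariant to time shift and rescaling", {
  set.seed(13)
  a <- sort(runif(40, 0, 20)); b <- sort(runif(60, 0, 20))
  d0 <- spikeDistance(a, b, duration = 20)
  expect_lt(abs(spikeDistance(a + 5, b + 5, duration = 20, start = 5) - d0),
            1e-12)
  for (c in c(0.001, 3, 1000)) {
    expect_lt(abs(spikeDistance(c * a, c * b, duration = c * 20) - d0), 1e-9)
  }
})

test_that("similarity transform and bounds behave as defined", {
  a <- spikeTrain(seq(0.5, 49.5, by = 0.5), duration = 50)
  expect_identical(rawSimilarity(a, a), 1)
  set.seed(17)
  for (i in 1:20) {
    x <- sort(runif(30, 0, 50)); y <- sort(runif(30, 0, 50))
    d <- spikeDistance(x, y, duration = 50)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(rawSimilarity(x, y, duration = 50), 1 - d)
  }
})

test_that("synchrony decreases monotonically with jitter", {
  jitters <- c(0, 0.005, 0.02, 0.1)
  means <- sapply(jitters, function(j) {
    mean(vapply(1:20, function(s) {
      base <- generatePoissonTrain(2, 100, seed = 1000 + s)
      pr <- generateCorrelatedPair(base, jitterSd = j, seed = s)
      rawSimilarity(pr$a, pr$b)
    }, 0))
  })
  expect_true(all(diff(means) < 0))
})

test_that("surrogate normalization is capped, deterministic and NA for silence", {
  tr <- generatePoissonTrain(2, 50, seed = 3)
  s1 <- normalizedSynchrony(tr, tr)
  expect_identical(as.numeric(s1), 1)
  expect_gt(attr(s1, "ratio"), 1)
  tr2 <- generatePoissonTrain(2, 50, seed = 4)
  expect_identical(as.numeric(normalizedSynchrony(tr, tr2)),
                   as.numeric(normalizedSynchrony(tr, tr2)))
  empty <- spikeTrain(numeric(0), duration = 50)
  expect_true(is.na(normalizedSynchrony(tr, empty)))
})

test_that("well synchrony scores every retained pair and summarizes", {
  trs <- lapply(1:4, function(i)
    generatePoissonTrain(2, 30, seed = 20 + i, electrodeId = paste0("e", i)))
  sess <- recordingSession("w1", "30m", trains = trs, duration = 30)
  feats <- data.frame(electrode = paste0("e", 1:4),
                      status = factor("included",
                                      levels = c("included", "inactive", "noisy")))
  res <- wellSynchrony(sess, feats, surrogateSpec(nSurrogates = 5, seed = 2))
  expect_identical(nrow(res$pairs), 6L)
  expect_identical(sum(res$histogram), 6L)
  expect_true(res$mean >= 0 && res$mean <= 1)

  # identical copies of one train give perfect mean synchrony
  base <- spikeTimes(trs[[1]])
  copies <- lapply(1:3, function(i)
    spikeTrain(base, duration = 30, electrodeId = paste0("e", i)))
  sessC <- recordingSession("w1", "30m", trains = copies, duration = 30)
  resC <- wellSynchrony(sessC, feats[1:3, , drop = FALSE],
                        surrogateSpec(nSurrogates = 5, seed = 2))
  expect_identical(resC$mean, 1)

  # fewer than two retained electrodes: flagged undefined
  expect_warning(
    resU <- wellSynchrony(sess, feats[1, , drop = FALSE],
                          surrogateSpec(nSurrogates = 5, seed = 2)),
    "fewer than 2")
  expect_true(is.na(resU$mean))
})

test_that("independent-pair synchrony is stable across seeds", {
  means <- vapply(1:20, function(s) {
    a <- generatePoissonTrain(2, 60, seed = 3000 + s)
    b <- generatePoissonTrain(2, 60, seed = 6000 + s)
    as.numeric(normalizedSynchrony(a, b, surrogateSpec(nSurrogates = 10,
                                                       seed = s)))
  }, 0)
  expect_lt(sd(means), 0.05)
})
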