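test_that("bandpass filter attenuates out-of-band and preserves in-band tones", {
  p <- detectorParams()
  tt <- seq(0, 5, by = 1 / p@fs)
  slow <- sin(2 * pi * 1 * tt)
  mid <- sin(2 * pi * 100 * tt)
  # measure amplitude away from the filtfilt edge transients
  core <- seq(p@fs, length(tt) - p@fs)
  ampl <- function(x) sqrt(2) * sd(x[core])
  expect_lt(20 * log10(ampl(bandpassFilter(slow, p)) / ampl(slow)), -20)
  expect_lt(abs(ampl(bandpassFilter(mid, p)) / ampl(mid) - 1), 0.05)
  expect_equal(bandpassFilter(numeric(2000), p), numeric(2000))
  expect_error(detectorParams(bandpassHigh = 6000), "Nyquist|fs/2")
})

test_that("noise SD estimate is accurate and robust to spike contamination", {
  noise <- withr::with_seed(1, rnorm(60 * 10000))
  expect_lt(abs(estimateNoiseSd(noise, fs = 10000) - 1), 0.02)
  # sparse large spikes at 0.5 Hz barely move the robust estimate
  contaminated <- injectSpikes(noise, seq(1, 59, by = 2), 8, fs = 10000)
  expect_lt(abs(estimateNoiseSd(contaminated, fs = 10000) - 1), 0.05)
  expect_identical(estimateNoiseSd(rep(3, 1000), fs = 1000), 0)
  expect_error(detectSpikes(rep(3, 1000), detectorParams(), noiseSd = 0),
               "positive")
})

test_that("detector recovers injected spikes above threshold and not below", {
  p <- detectorParams()
  trueTimes <- seq(0.5, 59.5, by = 1)
  hits <- function(found, truth, tol = 2e-3)
    sum(vapply(truth, function(x) any(abs(found - x) <= tol), TRUE))
  for (s in 1:10) {
    noise <- withr::with_seed(s, rnorm(60 * p@fs))
    sig <- estimateNoiseSd(noise, fs = p@fs)
    tr8 <- injectSpikes(noise, trueTimes, 8 * sig, fs = p@fs)
    st <- detectSpikes(tr8, p, noiseSd = sig)
    rec <- hits(spikeTimes(st), trueTimes) / length(trueTimes)
    prec <- hits(trueTimes, spikeTimes(st)) / max(1, nSpikes(st))
    expect_gte(rec, 0.95)
    expect_gte(prec, 0.95)
    tr3 <- injectSpikes(noise, trueTimes, 3 * sig, fs = p@fs)
    st3 <- detectSpikes(tr3, p, noiseSd = sig)
    expect_lte(hits(spikeTimes(st3), trueTimes) / length(trueTimes), 0.5)
  }
})

test_that("detector output is empty on a silent trace and obeys the refractory", {
  p <- detectorParams()
  expect_identical(nSpikes(detectSpikes(numeric(10000), p, noiseSd = 1)), 0L)
  noise <- withr::with_seed(2, rnorm(30 * p@fs))
  sig <- estimateNoiseSd(noise, fs = p@fs)
  st <- detectSpikes(injectSpikes(noise, seq(0.5, 29.5, by = 0.5), 8 * sig,
                                  fs = p@fs), p, noiseSd = sig)
  expect_true(all(diff(spikeTimes(st)) >= p@refractory - 1e-9))
  validObject(st)
})

test_that("detection flips exactly at the configured threshold multiple", {
  p <- detectorParams()
  calib <- withr::with_seed(3, rnorm(60 * p@fs))
  sig <- estimateNoiseSd(calib, fs = p@fs)
  flat <- numeric(60 * p@fs)
  tms <- seq(1, 58, length.out = 20)
  detected <- vapply((10:100) / 10, function(a)
    nSpikes(detectSpikes(injectSpikes(flat, tms, a * sig, fs = p@fs), p,
                         noiseSd = sig)) == 20L, TRUE)
  grid <- (10:100) / 10
  expect_equal(min(grid[detected]), 6.5)
  expect_true(all(detected[grid >= 6.5]))
  expect_false(any(detected[grid < 6.5]))
})
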