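# Independent oracles used by the tests. These deliberately share no code
# with the package implementations they check.

# Dense-grid numeric integration of the bivariate spike-train
# dissimilarity profile: evaluates the instantaneous profile at midpoints
# of a regular grid and averages. The package integrates the piecewise
# profile exactly instead.
gridSpikeDistance <- function(a, b, T, dt = 1e-4) {
  ta <- unique(c(0, a[a >= 0 & a <= T], T))
  tb <- unique(c(0, b[b >= 0 & b <= T], T))
  tt <- seq(dt / 2, T - dt / 2, by = dt)
  refs <- function(tr, t) {
    iP <- findInterval(t, tr)
    list(tP = tr[pmax(iP, 1L)], tF = tr[pmin(iP + 1L, length(tr))])
  }
  nn <- function(x, v) {
    i <- findInterval(x, v)
    pmin(ifelse(i >= 1, abs(x - v[pmax(i, 1)]), Inf),
         ifelse(i < length(v), abs(v[pmin(i + 1, length(v))] - x), Inf))
  }
  ra <- refs(ta, tt); rb <- refs(tb, tt)
  xa <- ra$tF - ra$tP; xb <- rb$tF - rb$tP
  Sa <- (nn(ra$tP, tb) * (ra$tF - tt) + nn(ra$tF, tb) * (tt - ra$tP)) / xa
  Sb <- (nn(rb$tP, ta) * (rb$tF - tt) + nn(rb$tF, ta) * (tt - rb$tP)) / xb
  mean((Sa * xb + Sb * xa) / (2 * ((xa + xb) / 2)^2))
}

# Exhaustive max-interval burst oracle: enumerates every index window
# satisfying the start/extension rules (O(n^2)), selects maximal disjoint
# windows greedily from the left, merges to a fixed point, then filters.
# Returns a data.frame(firstIndex, lastIndex).
bruteForceBursts <- function(times, maxBeginIsi = 0.1, maxEndIsi = 0.2,
                             minIbi = 0.5, minDuration = 0.05,
                             minSpikes = 6, eps = 1e-9) {
  n <- length(times)
  empty <- data.frame(firstIndex = integer(0), lastIndex = integer(0))
  if (n < 2L) return(empty)
  d <- diff(times)
  valid <- function(i, j)
    d[i] <= maxBeginIsi + eps && all(d[i:(j - 1)] <= maxEndIsi + eps)
  wins <- expand.grid(i = seq_len(n - 1), j = seq_len(n))
  wins <- wins[wins$j > wins$i, ]
  ok <- mapply(valid, wins$i, wins$j)
  wins <- wins[ok, , drop = FALSE]
  # greedy maximal disjoint selection from the left
  first <- integer(0); last <- integer(0)
  lo <- 1L
  while (nrow(wins)) {
    cand <- wins[wins$i >= lo, , drop = FALSE]
    if (!nrow(cand)) break
    i0 <- min(cand$i)
    j0 <- max(cand$j[cand$i == i0])
    first <- c(first, i0); last <- c(last, j0)
    lo <- j0 + 1L
    wins <- wins[wins$i > j0, , drop = FALSE]
  }
  # merge to fixed point
  repeat {
    if (length(first) < 2L) break
    gaps <- times[first[-1]] - times[last[-length(last)]]
    k <- which(gaps < minIbi - eps)
    if (!length(k)) break
    k <- k[1]
    first <- first[-(k + 1)]
    last <- last[-k]
  }
  keep <- (times[last] - times[first] >= minDuration - eps) &
    (last - first + 1L >= minSpikes)
  data.frame(firstIndex = first[keep], lastIndex = last[keep])
}

# Random spike train covering mixed regimes: tonic, clustered, or sparse.
randomTestTrain <- function(maxSpikes = 50) {
  n <- sample.int(maxSpikes, 1)
  regime <- sample(c("tonic", "clustered", "sparse"), 1)
  t <- switch(regime,
    tonic = cumsum(runif(n, 0.01, 0.4)),
    clustered = {
      centers <- cumsum(runif(max(1, n %/% 5), 0.2, 2))
      sort(rep(centers, length.out = n) + runif(n, 0, 0.25))
    },
    sparse = sort(runif(n, 0, 60)))
  unique(t)
}
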