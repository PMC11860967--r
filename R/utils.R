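# Internal helpers shared across modules.

# Absolute tolerance for interval comparisons on spike times (seconds).
# Spike times are stored as float64 built from ms-grid arithmetic; 1e-9 s is
# far below any physical timing resolution and far above accumulated rounding.
.TIME_EPS <- 1e-9

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded generators never perturb the
#' session stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a master seed plus string labels; used to give
# every (well, timepoint, electrode) its own reproducible substream.
hashSeed <- function(masterSeed, ...) {
  s <- paste(c(as.character(masterSeed), vapply(list(...), as.character, "")),
             collapse = "\x1f")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Nearest-neighbour distances from each x to sorted vector v (v non-empty).
nnDist <- function(x, v) {
  i <- findInterval(x, v)
  lo <- ifelse(i >= 1L, abs(x - v[pmax(i, 1L)]), Inf)
  hi <- ifelse(i < length(v), abs(v[pmin(i + 1L, length(v))] - x), Inf)
  pmin(lo, hi)
}

.assertScalarNum <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= min)
    stop(sprintf("'%s' must be > %g", name, min), call. = FALSE)
  if (!strict && x < min)
    stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}
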