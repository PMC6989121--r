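# shared internal helpers

# strictly-increasing check used by every timestamped stream
assert_strictly_increasing <- function(t, what = "timestamps") {
  if (length(t) > 1L && any(diff(t) <= 0)) {
    abort(sprintf("non-monotone %s", what))
  }
  invisible(t)
}

# nearest index in sorted `haystack` for each value in `needles`
nearest_index <- function(needles, haystack) {
  lo <- findInterval(needles, haystack)
  lo <- pmax(lo, 1L)
  hi <- pmin(lo + 1L, length(haystack))
  use_hi <- abs(haystack[hi] - needles) < abs(haystack[lo] - needles)
  ifelse(use_hi, hi, lo)
}

# zero-phase Butterworth low-pass; falls back to the identity when the
# cutoff is at/above Nyquist (nothing to remove)
lowpass <- function(x, rate_hz, cutoff_hz, order = 2L) {
  w <- cutoff_hz / (rate_hz / 2)
  if (!is.finite(w) || w >= 1) return(x)
  bf <- signal::butter(order, w, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# deterministic sub-seed derivation: one global seed fans out to named
# per-component streams so each sub-generator is independently reproducible
derive_seed <- function(seed, stream) {
  offsets <- c(
    events = 1L, ensemble = 2L, jitter = 3L, trace_noise = 4L,
    accel_noise = 5L, movement = 6L, rearing = 7L, turning = 8L,
    stim = 9L, misc = 10L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) + off * 1000003) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
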