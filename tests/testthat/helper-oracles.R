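# Independent brute-force oracles. Deliberately naive (O(n^2) loops over
# every grid point / onset / pair) so they share no code path with the
# package implementations they cross-check.

brute_kernel_sum <- function(onsets, grid, h) {
  S <- numeric(length(grid))
  for (i in seq_along(grid)) {
    for (on in onsets) {
      d <- grid[i] - on
      if (abs(d) <= h) S[i] <- S[i] + (1 - (d / h)^2)
    }
  }
  S
}

brute_sync_intervals <- function(grid, S, threshold, dt) {
  out <- list()
  i <- 1L
  n <- length(grid)
  while (i <= n) {
    if (S[i] > threshold) {
      j <- i
      while (j < n && S[j + 1L] > threshold) j <- j + 1L
      out[[length(out) + 1L]] <- c(grid[i], grid[j] + dt)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# co-firing counts by triple loop over (interval x pair), once per interval
brute_pair_counts <- function(intervals, events) {
  ids <- sort(unique(events$cell_id))
  counts <- list()
  for (iv in intervals) {
    present <- character(0)
    for (id in ids) {
      on <- events$onset_s[events$cell_id == id]
      hit <- FALSE
      for (x in on) if (x >= iv[1] && x < iv[2]) hit <- TRUE
      if (hit) present <- c(present, id)
    }
    if (length(present) >= 2L) {
      for (a in seq_along(present)) {
        for (b in seq_along(present)) {
          if (a < b) {
            key <- paste(present[a], present[b], sep = "|")
            counts[[key]] <- (counts[[key]] %||% 0L) + 1L
          }
        }
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive nearest-neighbor for stream alignment
brute_nearest <- function(needles, haystack) {
  vapply(needles, function(x) which.min(abs(haystack - x)), integer(1))
}

# interval scan oracle for threshold epochs with hysteresis
brute_hysteresis <- function(t, x, th_on, th_off) {
  eps <- list()
  inside <- FALSE
  t0 <- NA_real_
  for (i in seq_along(x)) {
    if (!inside && x[i] > th_on) {
      inside <- TRUE; t0 <- t[i]
    } else if (inside && x[i] < th_off) {
      inside <- FALSE; eps[[length(eps) + 1L]] <- c(t0, t[i])
    }
  }
  if (inside) eps[[length(eps) + 1L]] <- c(t0, t[length(t)])
  eps
}

# fraction of detected intervals matching planted intervals (midpoint rule)
match_epochs <- function(detected, planted, tol = 0.5) {
  if (nrow(planted) == 0L) return(NA_real_)
  hits <- vapply(seq_len(nrow(planted)), function(i) {
    mid <- (planted$t0[i] + planted$t1[i]) / 2
    any(detected$t_start - tol <= mid & detected$t_end + tol >= mid)
  }, logical(1))
  mean(hits)
}
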