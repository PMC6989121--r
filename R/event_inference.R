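# Calcium-event onset extraction at sub-frame resolution and the per-cell
# descriptive statistics derived from it (event rates, half-decay times,
# Z-scored traces).
#
# Onsets are found by cross-correlating each trace with a unit-energy
# transient template; local maxima of the filter output above
# threshold * sigma_noise become events, and parabolic interpolation through
# the three samples around each maximum gives sub-frame timing. With a
# unit-energy template, white noise passes through the filter with unchanged
# standard deviation, so sigma_noise estimated on the raw trace calibrates
# the filtered signal directly.

#' Onset-detection parameters
#'
#' @param rise_tau_s,t_half_s template transient shape (see [gcamp_kernel()]).
#' @param threshold detection threshold in units of the noise SD (default 3).
#' @param refractory_s minimum separation between events; when two detections
#'   are closer, the earlier one is kept (default 0.2 s).
#' @param noise_estimator `"mad_diff"` (median absolute deviation of the
#'   first difference, divided by sqrt(2); robust to transients) or `"sd"`.
#' @return An `onset_params` list.
#' @export
onset_params <- function(rise_tau_s = 0.02, t_half_s = 0.3, threshold = 3,
                         refractory_s = 0.2,
                         noise_estimator = c("mad_diff", "sd")) {
  stopifnot(threshold > 0, refractory_s >= 0)
  structure(
    list(rise_tau_s = rise_tau_s, t_half_s = t_half_s, threshold = threshold,
         refractory_s = refractory_s,
         noise_estimator = match.arg(noise_estimator)),
    class = "onset_params"
  )
}

estimate_noise_sd <- function(x, estimator) {
  switch(estimator,
    mad_diff = mad(diff(x)) / sqrt(2),
    sd = sd(x)
  )
}

#' Detect calcium-event onsets in one trace
#'
#' @param trace numeric fluorescence (or deconvolved) vector for one cell.
#' @param frame_ts per-frame timestamps, strictly increasing.
#' @param params an [onset_params()].
#' @return A tibble with columns `onset_s` (sub-frame seconds) and
#'   `amplitude` (peak minus local baseline, a.u.). A constant trace yields
#'   zero rows; NaN/NA in the trace is an error.
#' @export
detect_onsets <- function(trace, frame_ts, params = onset_params()) {
  if (anyNA(trace) || any(!is.finite(trace))) {
    abort("trace contains non-finite values")
  }
  stopifnot(length(trace) == length(frame_ts), length(trace) >= 10L)
  assert_strictly_increasing(frame_ts)
  empty <- tibble(onset_s = numeric(0), amplitude = numeric(0))
  if (diff(range(trace)) == 0) return(empty)

  dt <- median(diff(frame_ts))
  x <- trace - median(trace)
  sigma <- estimate_noise_sd(x, params$noise_estimator)
  if (sigma <= 0) sigma <- sd(x)
  if (sigma <= 0) return(empty)

  # unit-energy template sampled at the frame grid
  tpl_t <- seq(0, 6 * params$t_half_s + 5 * params$rise_tau_s, by = dt)
  tpl <- gcamp_kernel(tpl_t, params$rise_tau_s, params$t_half_s)
  tpl <- tpl / sqrt(sum(tpl^2))
  m <- length(tpl)

  # cross-correlation: c[i] = sum_j x[i + j - 1] * tpl[j]; peak at the onset
  # (convolve(x, y, "open") is convolution with rev(y), so c[i] sits at
  # output index i + m - 1)
  n <- length(x)
  cc <- stats::convolve(x, tpl, type = "open")
  cc <- cc[m:(m + n - 1L)]

  thr <- params$threshold * sigma
  is_peak <- cc > thr &
    cc >= c(-Inf, cc[-n]) &
    cc > c(cc[-1L], -Inf)
  cand <- which(is_peak)
  if (length(cand) == 0L) return(empty)

  # prominence gate: the slowly decaying transient tail keeps the filter
  # output high after an onset, so noise ripples there form local maxima;
  # a candidate is kept only if the output rose by >= threshold * sigma
  # from the trough since the previously accepted event
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) == 0L) {
      peaks <- i
    } else {
      trough <- min(cc[tail(peaks, 1L):i])
      if (cc[i] - trough >= thr) peaks <- c(peaks, i)
    }
  }

  # sub-frame timing: parabola through the 3 samples around each maximum
  onset_f <- vapply(peaks, function(i) {
    if (i <= 1L || i >= n) return(as.numeric(i))
    denom <- cc[i - 1L] - 2 * cc[i] + cc[i + 1L]
    delta <- if (denom >= 0) 0 else 0.5 * (cc[i - 1L] - cc[i + 1L]) / denom
    i + max(min(delta, 0.5), -0.5)
  }, numeric(1))
  onset_s <- frame_ts[1] + (onset_f - 1) * dt

  # refractory: keep the earlier event of any pair closer than refractory_s
  keep <- logical(length(onset_s))
  last <- -Inf
  for (j in seq_along(onset_s)) {
    if (onset_s[j] - last >= params$refractory_s) {
      keep[j] <- TRUE
      last <- onset_s[j]
    }
  }
  onset_s <- onset_s[keep]

  amp <- vapply(onset_s, function(on) {
    post <- trace[frame_ts >= on & frame_ts <= on + 0.5]
    pre <- trace[frame_ts >= on - 0.3 & frame_ts < on]
    base <- if (length(pre) > 0L) median(pre) else median(trace)
    if (length(post) > 0L) max(post) - base else NA_real_
  }, numeric(1))

  tibble(onset_s = onset_s, amplitude = amp)
}

#' Detect onsets for every cell of a trace matrix
#'
#' @param tm a [trace_matrix()].
#' @param params an [onset_params()]; `t_half_s` may be a named per-region
#'   vector, in which case each cell uses its region's template.
#' @return An event table: tibble with columns `cell_id`, `region`,
#'   `onset_s`, `amplitude`, sorted by cell then time.
#' @export
detect_events <- function(tm, params = onset_params()) {
  stopifnot(inherits(tm, "trace_matrix"))
  th <- params$t_half_s
  purrr::map2_dfr(seq_len(nrow(tm$values)), tm$cells$region, function(i, r) {
    p <- params
    if (length(th) > 1L) p$t_half_s <- th[[r]]
    ev <- detect_onsets(tm$values[i, ], tm$t, p)
    if (nrow(ev) == 0L) return(NULL)
    dplyr::bind_cols(tibble(cell_id = tm$cells$cell_id[i], region = r), ev)
  })
}

#' Per-cell event rate
#'
#' @param events event table (`cell_id`, `onset_s`, optionally `region`).
#' @param duration_s session duration in seconds, > 0.
#' @param cell_ids optional full roster so that cells with zero events appear
#'   with rate 0.
#' @return A tibble with columns `cell_id` (and `region` if present),
#'   `n_events`, `rate_hz`.
#' @export
event_rate <- function(events, duration_s, cell_ids = NULL) {
  stopifnot(duration_s > 0)
  out <- dplyr::summarise(
    dplyr::group_by(events, dplyr::across(dplyr::any_of(c("cell_id", "region")))),
    n_events = dplyr::n(), .groups = "drop"
  )
  if (!is.null(cell_ids)) {
    roster <- if (is.data.frame(cell_ids)) {
      cell_ids
    } else {
      tibble(cell_id = cell_ids)
    }
    out <- dplyr::left_join(roster, out,
                            by = intersect(names(roster), names(out)))
    out$n_events[is.na(out$n_events)] <- 0L
  }
  dplyr::mutate(out, rate_hz = .data$n_events / duration_s)
}

#' Half-decay time of isolated transients
#'
#' For each event isolated from its neighbors by at least `isolation_s`, the
#' peak is the trace maximum within 0.5 s after onset, the baseline the
#' median of the 0.3 s before onset, and `t_half` the first post-peak time at
#' which the trace falls to baseline + (peak - baseline) / 2, with linear
#' interpolation between the bracketing samples. Events that never fall to
#' half within `max_follow_s` are reported censored (`t_half_s = NA`).
#'
#' @param trace one cell's fluorescence vector.
#' @param frame_ts frame timestamps.
#' @param onsets event onset times for this cell (seconds).
#' @param isolation_s minimum distance to both neighboring events (default 1).
#' @param max_follow_s how far past the peak to search (default 3).
#' @return A tibble with one row per usable event: `onset_s`, `t_half_s`,
#'   `censored`; attribute `n_skipped` counts non-isolated events.
#' @export
half_decay_time <- function(trace, frame_ts, onsets, isolation_s = 1,
                            max_follow_s = 3) {
  onsets <- sort(onsets)
  if (length(onsets) == 0L) {
    out <- tibble(onset_s = numeric(0), t_half_s = numeric(0),
                  censored = logical(0))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  gap_prev <- c(Inf, diff(onsets))
  gap_next <- c(diff(onsets), Inf)
  usable <- gap_prev >= isolation_s & gap_next >= isolation_s

  rows <- lapply(onsets[usable], function(on) {
    pre <- trace[frame_ts >= on - 0.3 & frame_ts < on]
    base <- if (length(pre) > 0L) median(pre) else min(trace)
    win <- frame_ts >= on & frame_ts <= on + 0.5
    if (!any(win)) return(NULL)
    ipk <- which(win)[which.max(trace[win])]
    peak <- trace[ipk]
    t_peak <- frame_ts[ipk]
    # sub-frame peak refinement: parabola through the 3 samples around the
    # maximum (the true peak generally falls between frames); only valid for
    # a smooth, well-sampled peak -- both neighbors must sit above the half
    # level, otherwise (e.g. a step-sharp rise) the raw sample is kept
    half0 <- base + (peak - base) / 2
    if (ipk > 1L && ipk < length(trace) &&
        trace[ipk - 1L] >= half0 && trace[ipk + 1L] >= half0) {
      denom <- trace[ipk - 1L] - 2 * trace[ipk] + trace[ipk + 1L]
      if (denom < 0) {
        delta <- 0.5 * (trace[ipk - 1L] - trace[ipk + 1L]) / denom
        delta <- max(min(delta, 0.5), -0.5)
        dt <- frame_ts[ipk + 1L] - frame_ts[ipk]
        t_peak <- frame_ts[ipk] + delta * dt
        peak <- trace[ipk] - 0.25 * (trace[ipk - 1L] - trace[ipk + 1L]) * delta
      }
    }
    if (peak <= base) return(NULL)
    half <- base + (peak - base) / 2
    follow <- which(frame_ts > frame_ts[ipk] &
                      frame_ts <= frame_ts[ipk] + max_follow_s)
    if (length(follow) == 0L) {
      return(tibble(onset_s = on, t_half_s = NA_real_, censored = TRUE))
    }
    # a crossing must be confirmed by the following sample, so an isolated
    # noise dip below the half level does not end the decay early
    below <- follow[trace[follow] <= half]
    below <- below[below == max(follow) | (below + 1L) %in% below]
    if (length(below) == 0L) {
      return(tibble(onset_s = on, t_half_s = NA_real_, censored = TRUE))
    }
    i1 <- below[1L]
    i0 <- i1 - 1L
    # linear interpolation between the bracketing samples
    t_cross <- frame_ts[i0] + (half - trace[i0]) /
      (trace[i1] - trace[i0]) * (frame_ts[i1] - frame_ts[i0])
    tibble(onset_s = on, t_half_s = t_cross - t_peak, censored = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(onset_s = numeric(0), t_half_s = numeric(0),
                  censored = logical(0))
  }
  attr(out, "n_skipped") <- sum(!usable)
  out
}

#' Half-decay summary for a whole session
#'
#' Runs [half_decay_time()] per cell and summarises by region.
#'
#' @param tm a [trace_matrix()].
#' @param events event table from [detect_events()].
#' @inheritParams half_decay_time
#' @return A list with `events` (per-event tibble incl. `cell_id`, `region`)
#'   and `summary` (per-region median/mean/sd of `t_half_s`, counts).
#' @export
half_decay_summary <- function(tm, events, isolation_s = 1) {
  per_event <- purrr::map_dfr(unique(events$cell_id), function(id) {
    i <- match(id, tm$cells$cell_id)
    ons <- events$onset_s[events$cell_id == id]
    hd <- half_decay_time(tm$values[i, ], tm$t, ons, isolation_s = isolation_s)
    if (nrow(hd) == 0L) return(NULL)
    dplyr::bind_cols(tibble(cell_id = id, region = tm$cells$region[i]), hd)
  })
  if (nrow(per_event) == 0L) {
    return(list(events = per_event,
                summary = tibble(region = character(0))))
  }
  summary <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(per_event, !.data$censored), .data$region),
    n = dplyr::n(),
    median_t_half_s = median(.data$t_half_s),
    mean_t_half_s = mean(.data$t_half_s),
    sd_t_half_s = sd(.data$t_half_s),
    .groups = "drop"
  )
  summary$n_censored <- vapply(summary$region, function(r) {
    sum(per_event$censored & per_event$region == r)
  }, integer(1))
  list(events = per_event, summary = summary)
}

#' Z-score traces against a baseline window
#'
#' Each cell is standardized by the mean and SD of its samples inside
#' `baseline_window`. Cells with zero baseline SD are flagged and output as
#' all-zero rather than dividing by zero. Z-scoring is invariant to affine
#' rescaling of the input row.
#'
#' @param tm a [trace_matrix()].
#' @param baseline_window `c(t0, t1)` in seconds, half-open.
#' @return A `trace_matrix` of Z-scores; flagged cells are listed in
#'   `$cells$flag_zero_sigma`.
#' @export
zscore_traces <- function(tm, baseline_window) {
  stopifnot(inherits(tm, "trace_matrix"), length(baseline_window) == 2L)
  sel <- tm$t >= baseline_window[1] & tm$t < baseline_window[2]
  if (!any(sel)) abort("baseline window contains no frames")
  mu <- rowMeans(tm$values[, sel, drop = FALSE])
  sg <- apply(tm$values[, sel, drop = FALSE], 1L, sd)
  flag <- sg == 0 | !is.finite(sg)
  z <- (tm$values - mu) / ifelse(flag, 1, sg)
  z[flag, ] <- 0
  out <- trace_matrix(z, tm$t, tm$cells$cell_id, tm$cells$region,
                      frame_rate_hz = tm$frame_rate_hz)
  out$cells$flag_zero_sigma <- flag
  out
}
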