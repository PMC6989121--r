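# IMU behavior parsing: compound acceleration, SP-triggered acceleration
# classification with its random-trigger control, rearing and turning
# segmentation, and peri-event triggered averaging.

#' Compound acceleration signal
#'
#' `a_xyz = sqrt(x^2 + y^2 + z^2)`, the rotation-invariant magnitude of the
#' three-axis acceleration.
#'
#' @param acc an [accel_record()] (or tibble with `t`, `x`, `y`, `z`).
#' @return A tibble with columns `t`, `a` (g).
#' @export
compound_accel <- function(acc) {
  tibble(t = acc$t, a = sqrt(acc$x^2 + acc$y^2 + acc$z^2))
}

# sample rate of a uniform-ish series
series_rate <- function(t) 1 / median(diff(t))

#' Classify SP-triggered behavioral acceleration
#'
#' For each synchronous-pattern time, a snippet `[sp - win_s, sp + win_s]` of
#' the (low-pass-filtered) compound acceleration is cut out. The threshold is
#' `mean + 2*sigma` of the snippet's outer baseline -- the earliest
#' `baseline_frac` of the pre-window, farthest from the SP, so the baseline
#' is not contaminated by the movement itself. Categories:
#'
#' Under the default `criterion = "window_mean"`, a side "rises above
#' threshold" when the mean of its samples does -- the reading under which a
#' quiet baseline yields `no_change` (a pointwise maximum over a multi-second
#' window exceeds its own 2-sigma threshold on almost any stochastic
#' baseline). `criterion = "pointwise"` uses individual samples instead.
#' Categories:
#'
#' * `no_change` -- neither side nor the central band crosses the threshold;
#' * `post` / `pre` -- the side (`(sp + around_s, sp + win_s]` vs
#'   `[sp - win_s, sp - around_s)`) with the larger mean, provided it
#'   crosses;
#' * `around` -- only the central `+/- around_s` band crosses.
#'
#' Categories are mutually exclusive and exhaustive over the classified SPs;
#' SPs whose window does not fit inside the recording are dropped and
#' counted.
#'
#' @param a compound-acceleration tibble from [compound_accel()].
#' @param sp_times SP times (seconds).
#' @param win_s half-window length (default 2 s).
#' @param around_s central band half-width (default 0.15 s).
#' @param baseline_frac fraction of the pre-window used as baseline
#'   (default 0.25).
#' @param lp_cutoff_hz low-pass cutoff applied to `a` before thresholding
#'   (default 10 Hz; `Inf` disables). The cutoff is chosen so the filter's
#'   impulse spread stays well inside the `+/- around_s` band.
#' @param criterion `"window_mean"` (default) or `"pointwise"`.
#' @return A list: `classes` (tibble `sp_time`, `category`, `threshold`,
#'   `t_cross` of first supra-threshold sample or `NA`), `fractions`
#'   (tibble `category`, `n`, `fraction` over the four categories), and
#'   `n_dropped_edge`.
#' @export
classify_sp_triggers <- function(a, sp_times, win_s = 2, around_s = 0.15,
                                 baseline_frac = 0.25, lp_cutoff_hz = 10,
                                 criterion = c("window_mean", "pointwise")) {
  criterion <- match.arg(criterion)
  if (length(sp_times) == 0L) {
    return(list(
      classes = tibble(sp_time = numeric(0), category = character(0),
                       threshold = numeric(0), t_cross = numeric(0)),
      fractions = tibble(category = c("no_change", "post", "pre", "around"),
                         n = 0L, fraction = NA_real_),
      n_dropped_edge = 0L
    ))
  }
  rate <- series_rate(a$t)
  sig <- if (is.finite(lp_cutoff_hz)) lowpass(a$a, rate, lp_cutoff_hz) else a$a
  ok <- sp_times - win_s >= min(a$t) & sp_times + win_s <= max(a$t)
  n_dropped <- sum(!ok)

  rows <- lapply(sp_times[ok], function(sp) {
    rel <- a$t - sp
    snip <- rel >= -win_s & rel <= win_s
    rs <- rel[snip]
    vs <- sig[snip]
    base <- vs[rs <= -win_s * (1 - baseline_frac)]
    thr <- mean(base) + 2 * sd(base)
    pre_side <- rs < -around_s
    post_side <- rs > around_s
    mid_band <- abs(rs) <= around_s
    if (criterion == "window_mean") {
      pre_stat <- mean(vs[pre_side])
      post_stat <- mean(vs[post_side])
      mid_stat <- mean(vs[mid_band])
      pre_hit <- pre_stat > thr
      post_hit <- post_stat > thr
      mid_hit <- mid_stat > thr
    } else {
      over <- vs > thr
      pre_hit <- any(over & pre_side)
      post_hit <- any(over & post_side)
      mid_hit <- any(over & mid_band)
      pre_stat <- if (pre_hit) mean(vs[over & pre_side]) else -Inf
      post_stat <- if (post_hit) mean(vs[over & post_side]) else -Inf
    }
    category <- if (pre_hit || post_hit) {
      if (post_hit && (!pre_hit || post_stat >= pre_stat)) "post" else "pre"
    } else if (mid_hit) {
      "around"
    } else {
      "no_change"
    }
    over_any <- vs > thr
    tibble(sp_time = sp, category = category, threshold = thr,
           t_cross = if (any(over_any)) sp + min(rs[over_any]) else NA_real_)
  })
  classes <- dplyr::bind_rows(rows)
  cats <- c("no_change", "post", "pre", "around")
  fractions <- tibble(
    category = cats,
    n = vapply(cats, function(k) sum(classes$category == k), integer(1)),
    fraction = vapply(cats, function(k) mean(classes$category == k), numeric(1))
  )
  list(classes = classes, fractions = fractions, n_dropped_edge = n_dropped)
}

#' Random-trigger control for SP-triggered acceleration
#'
#' Compares the fraction of SP-triggered snippets whose post-window exceeds
#' `mean + 2*sigma` of baseline against the same fraction for uniformly drawn
#' random trigger times (edge-excluded), via a two-sample proportion test on
#' the per-trigger indicators. Degenerate tables (identical indicators in
#' both groups) return `p_value = 1`.
#'
#' @inheritParams classify_sp_triggers
#' @param n_triggers number of random triggers, >= 1.
#' @param seed RNG seed for the random trigger draw.
#' @return A tibble with one row: `frac_random`, `frac_sp`, `p_value`,
#'   `n_random`, `n_sp`.
#' @export
random_trigger_null <- function(a, sp_times, n_triggers = 100L, seed = 1L,
                                win_s = 2, around_s = 0.15,
                                baseline_frac = 0.25, lp_cutoff_hz = 10) {
  if (n_triggers < 1L) abort("n_triggers must be >= 1")
  rate <- series_rate(a$t)
  sig <- if (is.finite(lp_cutoff_hz)) lowpass(a$a, rate, lp_cutoff_hz) else a$a

  post_exceeds <- function(trig) {
    vapply(trig, function(tt) {
      rel <- a$t - tt
      snip <- rel >= -win_s & rel <= win_s
      rs <- rel[snip]
      vs <- sig[snip]
      base <- vs[rs <= -win_s * (1 - baseline_frac)]
      thr <- mean(base) + 2 * sd(base)
      any(vs[rs > around_s] > thr)
    }, logical(1))
  }

  rand_t <- with_seed(seed, {
    runif(n_triggers, min(a$t) + win_s, max(a$t) - win_s)
  })
  sp_ok <- sp_times[sp_times - win_s >= min(a$t) & sp_times + win_s <= max(a$t)]
  ind_r <- post_exceeds(rand_t)
  ind_s <- post_exceeds(sp_ok)
  p <- if (length(ind_s) == 0L) {
    NA_real_
  } else if (length(unique(c(ind_r, ind_s))) == 1L) {
    1
  } else {
    suppressWarnings(
      prop.test(c(sum(ind_s), sum(ind_r)),
                c(length(ind_s), length(ind_r)), correct = FALSE)$p.value
    )
  }
  tibble(
    frac_random = mean(ind_r),
    frac_sp = if (length(ind_s) > 0) mean(ind_s) else NA_real_,
    p_value = p,
    n_random = length(ind_r),
    n_sp = length(ind_s)
  )
}

# extend epoch bounds outward to where the signal falls to th_edge, so an
# epoch's duration approximates the full excursion rather than only its
# supra-hysteresis core
extend_epochs <- function(ep, t, x, th_edge) {
  if (nrow(ep) == 0L) return(ep)
  for (k in seq_len(nrow(ep))) {
    i0 <- findInterval(ep$t_start[k], t)
    while (i0 > 1L && x[i0 - 1L] > th_edge) i0 <- i0 - 1L
    i1 <- findInterval(ep$t_end[k], t)
    while (i1 < length(t) && x[i1 + 1L] > th_edge) i1 <- i1 + 1L
    ep$t_start[k] <- t[i0]
    ep$t_end[k] <- t[i1]
  }
  # extension can make neighbors touch; merge overlaps
  if (nrow(ep) > 1L) {
    keep <- c(TRUE, ep$t_start[-1L] > ep$t_end[-nrow(ep)])
    ep <- ep[keep, ]
  }
  ep
}

# hysteresis interval scan: entry above th_on, exit below th_off
hysteresis_epochs <- function(t, x, th_on, th_off) {
  out <- list()
  inside <- FALSE
  t0 <- NA_real_
  for (i in seq_along(x)) {
    if (!inside && x[i] > th_on) {
      inside <- TRUE
      t0 <- t[i]
    } else if (inside && x[i] < th_off) {
      inside <- FALSE
      out[[length(out) + 1L]] <- c(t0, t[i])
    }
  }
  if (inside) out[[length(out) + 1L]] <- c(t0, t[length(t)])
  if (length(out) == 0L) {
    return(tibble(t_start = numeric(0), t_end = numeric(0)))
  }
  m <- do.call(rbind, out)
  tibble(t_start = m[, 1], t_end = m[, 2])
}

#' Detect rearing epochs from the y accelerometer channel
#'
#' The y channel is low-pass filtered, then excursions that rise above
#' `theta_on` and return below `theta_off` (hysteresis) with a duration
#' inside `[min_dur_s, max_dur_s]` are rearing epochs.
#'
#' @param acc an [accel_record()].
#' @param theta_on,theta_off hysteresis thresholds in g (defaults 0.15 / 0.08,
#'   tuned on the synthetic rearing template).
#' @param theta_edge low edge threshold to which epoch bounds are extended
#'   outward, so durations cover the full excursion (default `theta_off / 2`).
#' @param lp_cutoff_hz low-pass cutoff (default 2 Hz).
#' @param min_dur_s,max_dur_s admissible epoch durations (defaults 0.5-10 s).
#' @return A list: `epochs` (tibble `kind`, `t_start`, `t_end`) and `stats`
#'   (tibble `n`, `rate_per_min`, `mean_duration_s`, `sd_duration_s`).
#' @export
detect_rearings <- function(acc, theta_on = 0.15, theta_off = 0.08,
                            theta_edge = theta_off / 2,
                            lp_cutoff_hz = 2, min_dur_s = 0.5,
                            max_dur_s = 10) {
  rate <- series_rate(acc$t)
  y <- lowpass(acc$y, rate, lp_cutoff_hz)
  ep <- hysteresis_epochs(acc$t, y, theta_on, theta_off)
  ep <- extend_epochs(ep, acc$t, y, theta_edge)
  dur <- ep$t_end - ep$t_start
  ep <- ep[dur >= min_dur_s & dur <= max_dur_s, ]
  ep <- dplyr::mutate(ep, kind = "rearing", .before = 1L)
  span_min <- (max(acc$t) - min(acc$t)) / 60
  list(
    epochs = ep,
    stats = tibble(
      n = nrow(ep),
      rate_per_min = nrow(ep) / span_min,
      mean_duration_s = if (nrow(ep) > 0) mean(ep$t_end - ep$t_start) else NA_real_,
      sd_duration_s = if (nrow(ep) > 1) sd(ep$t_end - ep$t_start) else NA_real_
    )
  )
}

#' Detect turning epochs from the x accelerometer channel
#'
#' Left/right turns appear as up-/downward deflections of the low-passed x
#' channel. Epochs start at the threshold crossing (`x > +theta` for
#' `turn_left`, `x < -theta` for `turn_right` under the default sign
#' convention) and end when the signal returns inside `+/- theta_off`;
#' epochs closer than `refractory_s` to the previous one are discarded.
#'
#' @param acc an [accel_record()].
#' @param theta threshold in g (default 0.15).
#' @param theta_off release threshold (default `theta / 2`).
#' @param lp_cutoff_hz low-pass cutoff (default 2 Hz).
#' @param refractory_s minimum separation between epoch starts (default 0.5).
#' @param positive_is_left sign convention; flipping it swaps all labels.
#' @return A tibble `kind` (`turn_left` / `turn_right`), `t_start`, `t_end`.
#' @export
detect_turns <- function(acc, theta = 0.15, theta_off = theta / 2,
                         lp_cutoff_hz = 2, refractory_s = 0.5,
                         positive_is_left = TRUE) {
  rate <- series_rate(acc$t)
  x <- lowpass(acc$x, rate, lp_cutoff_hz)
  left <- hysteresis_epochs(acc$t, x, theta, theta_off)
  right <- hysteresis_epochs(acc$t, -x, theta, theta_off)
  lab <- function(up) {
    if (up == positive_is_left) "turn_left" else "turn_right"
  }
  ep <- dplyr::bind_rows(
    dplyr::mutate(left, kind = lab(TRUE), .before = 1L),
    dplyr::mutate(right, kind = lab(FALSE), .before = 1L)
  )
  ep <- dplyr::arrange(ep, .data$t_start)
  if (nrow(ep) > 1L) {
    keep <- c(TRUE, diff(ep$t_start) >= refractory_s)
    ep <- ep[keep, ]
  }
  ep
}

#' Peri-event triggered average
#'
#' Cuts snippets of a signal around each trigger, resamples them onto a
#' uniform relative-time grid, and returns the pointwise mean and SEM plus
#' the latency of the mean's peak inside `[0, win_s]`. With a single trigger
#' the mean is the snippet and SEM is 0 by convention.
#'
#' @param t,v signal timestamps and values (e.g. a compound-acceleration
#'   series, one cell's trace, or a population mean).
#' @param triggers trigger times; triggers whose window does not fit are
#'   dropped and counted.
#' @param win_s half-window (snippets span `[-win_s, win_s]`).
#' @param dt_s relative-grid step; defaults to the signal's own sampling step.
#' @return An `eta` object: list with `rel_t`, `mean`, `sem`, `n_triggers`,
#'   `n_dropped`, `peak_latency_s`.
#' @export
event_triggered_average <- function(t, v, triggers, win_s = 2, dt_s = NULL) {
  stopifnot(length(t) == length(v))
  if (is.null(dt_s)) dt_s <- median(diff(t))
  ok <- triggers - win_s >= min(t) & triggers + win_s <= max(t)
  if (!any(ok)) abort("no trigger has a full window inside the signal")
  rel <- seq(-win_s, win_s, by = dt_s)
  snips <- vapply(triggers[ok], function(tr) {
    approx(t, v, xout = tr + rel, rule = 2)$y
  }, numeric(length(rel)))
  snips <- matrix(snips, nrow = length(rel))
  mu <- rowMeans(snips)
  n <- ncol(snips)
  sem <- if (n > 1L) apply(snips, 1L, sd) / sqrt(n) else numeric(length(rel))
  post <- rel >= 0
  structure(
    list(rel_t = rel, mean = mu, sem = sem, n_triggers = n,
         n_dropped = sum(!ok),
         peak_latency_s = rel[post][which.max(mu[post])]),
    class = "eta"
  )
}

#' @export
print.eta <- function(x, ...) {
  cat(sprintf(
    "<eta> %d triggers (%d dropped), window +/- %g s, peak latency %.3f s\n",
    x$n_triggers, x$n_dropped, max(x$rel_t), x$peak_latency_s
  ))
  invisible(x)
}

#' @export
tidy.eta <- function(x, ...) {
  tibble(rel_t = x$rel_t, mean = x$mean, sem = x$sem)
}

#' @export
glance.eta <- function(x, ...) {
  tibble(n_triggers = x$n_triggers, n_dropped = x$n_dropped,
         peak_latency_s = x$peak_latency_s)
}
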