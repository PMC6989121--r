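# Optogenetic stimulus-response analyses: trial construction around stimuli,
# mean+2*sigma responder detection on trial-averaged traces, sigmoid-fit
# onset latency, paired-t three-way modulation classification, and
# movement-locked pre/post window means.

#' Build a trial tensor around stimulation times
#'
#' Cuts `[-pre_s, post_s]` snippets of every cell's trace around each
#' stimulus (aligned to stimulus onset, or to offset with
#' `align = "offset"`). Trials overlapping the recording edges are dropped
#' and counted.
#'
#' @param tm a [trace_matrix()].
#' @param stim a [stim_log()].
#' @param pre_s,post_s window extents (seconds, both positive).
#' @param align `"onset"` or `"offset"`.
#' @return A `trial_tensor`: list with `data` (cells x trials x time array),
#'   `rel_t`, `cells` (roster tibble), `stim` (retained stimuli),
#'   `pre_s`, `post_s`, `align`, `n_dropped`.
#' @export
build_trials <- function(tm, stim, pre_s = 2, post_s = 3,
                         align = c("onset", "offset")) {
  align <- match.arg(align)
  stopifnot(inherits(tm, "trace_matrix"), pre_s > 0, post_s > 0)
  ref <- stim$onset_s + if (align == "offset") stim$duration_s else 0
  ok <- ref - pre_s >= min(tm$t) & ref + post_s <= max(tm$t)
  if (!any(ok)) abort("no stimulus has a full trial window inside the recording")
  ref <- ref[ok]
  dt <- 1 / tm$frame_rate_hz
  rel <- seq(-pre_s, post_s, by = dt)
  n_cells <- nrow(tm$values)
  arr <- array(NA_real_, dim = c(n_cells, length(ref), length(rel)))
  for (i in seq_len(n_cells)) {
    for (j in seq_along(ref)) {
      arr[i, j, ] <- approx(tm$t, tm$values[i, ], xout = ref[j] + rel,
                            rule = 2)$y
    }
  }
  structure(
    list(data = arr, rel_t = rel, cells = tm$cells,
         stim = as_tibble(stim)[ok, ], pre_s = pre_s, post_s = post_s,
         align = align, n_dropped = sum(!ok)),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf(
    "<trial_tensor> %d cells x %d trials x %d samples, [%g, %g] s around stimulus %s (%d trials dropped)\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], -x$pre_s, x$post_s,
    x$align, x$n_dropped
  ))
  invisible(x)
}

#' @export
tidy.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    cell_id = rep(x$cells$cell_id, times = d[2] * d[3]),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    rel_t = rep(x$rel_t, each = d[1] * d[2]),
    value = as.numeric(x$data)
  )
}

# trial-averaged traces: cells x time
trial_mean <- function(tt) {
  apply(tt$data, c(1L, 3L), mean)
}

#' Classify responder cells (mean + 2 sigma rule)
#'
#' A cell is a responder when the maximum of its trial-averaged trace inside
#' the response window exceeds `mean + 2*sigma` of its pre-stimulus
#' baseline. The baseline statistics pool the raw per-trial pre-stimulus
#' samples (`rel_t < 0` across all trials): sigma then measures single-trial
#' spontaneous variability -- including spontaneous calcium transients -- so
#' a response has to exceed what ongoing activity reaches, not merely the
#' much smaller fluctuation left in the trial average. When the baseline SD
#' is exactly zero the threshold degenerates to the baseline mean. The
#' response window defaults to stimulus offset to offset + 1.5 s.
#'
#' For responders, the onset is obtained by fitting a sigmoid to the rise
#' phase of the trial-averaged trace (stimulus onset up to the averaged
#' peak) and taking the `mean + 1*sigma` crossing of the fit
#' ([sigmoid_onset()]).
#'
#' @param tt a [build_trials()] tensor (onset-aligned).
#' @param response_window `c(t0, t1)` relative to stimulus onset; `NULL` for
#'   the default offset .. offset + 1.5 s.
#' @param fit_onset also fit [sigmoid_onset()] for each responder.
#' @return A list: `calls` (tibble `cell_id`, `is_responder`,
#'   `peak_latency_s`, `onset_s`, `onset_flag`) and `responder_fraction`.
#' @export
classify_responders <- function(tt, response_window = NULL, fit_onset = TRUE) {
  stopifnot(inherits(tt, "trial_tensor"))
  stim_dur <- median(tt$stim$duration_s)
  if (is.null(response_window)) {
    response_window <- c(stim_dur, stim_dur + 1.5)
  }
  avg <- trial_mean(tt)
  rel <- tt$rel_t
  pre <- rel < 0
  if (sum(pre) < 10L) abort("pre-stimulus window has fewer than 10 samples")
  win <- rel >= response_window[1] & rel <= response_window[2]
  rows <- lapply(seq_len(nrow(avg)), function(i) {
    base <- as.numeric(tt$data[i, , pre])
    thr <- mean(base) + 2 * sd(base)
    post <- avg[i, win]
    is_resp <- any(post > thr)
    pk <- rel[win][which.max(post)]
    onset <- NA_real_
    flag <- NA_character_
    if (is_resp && fit_onset) {
      # fit only the rise phase: stimulus onset up to the averaged peak
      rise <- rel >= 0 & rel <= pk
      if (sum(rise) >= 5L) {
        fit <- sigmoid_onset(rel[rise], avg[i, rise],
                             baseline_mean = mean(base),
                             baseline_sd = sd(base))
        onset <- fit$onset_s
        flag <- fit$flag
      }
    }
    tibble(cell_id = tt$cells$cell_id[i], is_responder = is_resp,
           peak_latency_s = pk, onset_s = onset, onset_flag = flag)
  })
  calls <- dplyr::bind_rows(rows)
  list(calls = calls, responder_fraction = mean(calls$is_responder))
}

#' Sigmoid-fit response onset
#'
#' Fits a 4-parameter logistic `f(t) = b + A / (1 + exp(-(t - t0) / s))` to a
#' response snippet by least squares (initialized at `b = baseline mean`,
#' `A = peak - b`, `t0 =` half-rise sample, `s = 0.1` s) and returns the
#' smallest `t` with `f(t) > baseline_mean + baseline_sd`, solved in closed
#' form from the fitted parameters. If the fit fails the first raw-sample
#' crossing is used and flagged; if that also fails the onset is absent.
#'
#' @param t,v snippet times (seconds, increasing) and values.
#' @param baseline_mean,baseline_sd pre-stimulus baseline statistics.
#' @return A list: `onset_s` (or `NA`), `flag` (`"fit"`, `"raw_crossing"`, or
#'   `"none"`), `fit` (the `nls` object or `NULL`).
#' @export
sigmoid_onset <- function(t, v, baseline_mean, baseline_sd) {
  thr <- baseline_mean + baseline_sd
  raw_cross <- t[which(v > thr)[1]]

  b0 <- baseline_mean
  A0 <- max(v) - b0
  half <- b0 + A0 / 2
  t00 <- t[which(v >= half)[1]]
  if (is.na(t00)) t00 <- t[ceiling(length(t) / 2)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + A / (1 + exp(-(t - t0) / s)),
      start = list(b = b0, A = A0, t0 = t00, s = 0.1),
      lower = c(-Inf, 1e-12, min(t) - diff(range(t)), 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- as.list(coef(fit))
    # f(t) > thr  <=>  t > t0 - s * log(A / (thr - b) - 1) when b < thr < b+A
    if (thr <= p$b) {
      onset <- min(t)
    } else if (thr >= p$b + p$A) {
      onset <- NA_real_
    } else {
      onset <- p$t0 - p$s * log(p$A / (thr - p$b) - 1)
    }
    if (!is.na(onset) && onset >= min(t) && onset <= max(t)) {
      return(list(onset_s = onset, flag = "fit", fit = fit))
    }
  }
  if (!is.na(raw_cross)) {
    return(list(onset_s = raw_cross, flag = "raw_crossing", fit = fit))
  }
  list(onset_s = NA_real_, flag = "none", fit = fit)
}

#' Three-way modulation classification (paired t-test)
#'
#' For each cell, per-trial means of the pre-stimulus window (`rel_t < 0`)
#' and the stimulation window (`0 <= rel_t < duration`) are compared with a
#' paired t-test across trials. `p < alpha` splits into `decreased` /
#' `increased` by the sign of the mean difference; otherwise `unchanged`.
#' Zero-variance differences give `p = 1` (deterministic convention). Event
#' rates during stimulation are attached when an event table is supplied.
#'
#' @param tt an onset-aligned [build_trials()] tensor.
#' @param events optional event table (`cell_id`, `onset_s`) for per-cell
#'   stimulation-window event rates.
#' @param alpha significance level (default 0.05, uncorrected, matching the
#'   per-cell criterion; set `p_adjust = "BH"` to correct).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A list: `calls` (tibble `cell_id`, `class`, `p_value`,
#'   `mean_pre`, `mean_stim`, `event_rate_stim_hz`), `fractions`
#'   (per-class tibble `n`, `fraction`, `mean_rate_hz`).
#' @export
classify_modulation <- function(tt, events = NULL, alpha = 0.05,
                                p_adjust = "none") {
  stopifnot(inherits(tt, "trial_tensor"))
  d <- dim(tt$data)
  if (d[2] < 2L) abort("classify_modulation needs at least 2 trials")
  stim_dur <- median(tt$stim$duration_s)
  rel <- tt$rel_t
  pre <- rel < 0
  dur_win <- rel >= 0 & rel < stim_dur

  stim_windows <- tibble(t0 = tt$stim$onset_s,
                         t1 = tt$stim$onset_s + tt$stim$duration_s)
  total_stim_s <- sum(stim_windows$t1 - stim_windows$t0)

  rows <- lapply(seq_len(d[1]), function(i) {
    m_pre <- apply(tt$data[i, , pre, drop = FALSE], 2L, mean)
    m_stim <- apply(tt$data[i, , dur_win, drop = FALSE], 2L, mean)
    diffs <- m_stim - m_pre
    p <- if (sd(diffs) == 0 || !is.finite(sd(diffs))) {
      1
    } else {
      t.test(m_stim, m_pre, paired = TRUE)$p.value
    }
    rate <- NA_real_
    if (!is.null(events)) {
      on <- events$onset_s[events$cell_id == tt$cells$cell_id[i]]
      n_in <- sum(vapply(on, function(x) {
        any(x >= stim_windows$t0 & x < stim_windows$t1)
      }, logical(1)))
      rate <- n_in / total_stim_s
    }
    tibble(cell_id = tt$cells$cell_id[i], p_value = p,
           mean_pre = mean(m_pre), mean_stim = mean(m_stim),
           event_rate_stim_hz = rate)
  })
  calls <- dplyr::bind_rows(rows)
  p_used <- stats::p.adjust(calls$p_value, method = p_adjust)
  calls$class <- ifelse(
    p_used >= alpha, "unchanged",
    ifelse(calls$mean_stim > calls$mean_pre, "increased", "decreased")
  )
  cls <- c("decreased", "unchanged", "increased")
  fractions <- tibble(
    class = cls,
    n = vapply(cls, function(k) sum(calls$class == k), integer(1)),
    fraction = vapply(cls, function(k) mean(calls$class == k), numeric(1)),
    mean_rate_hz = vapply(cls, function(k) {
      r <- calls$event_rate_stim_hz[calls$class == k]
      if (length(r) == 0L || all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
    }, numeric(1))
  )
  list(calls = calls[c("cell_id", "class", "p_value", "mean_pre",
                       "mean_stim", "event_rate_stim_hz")],
       fractions = fractions)
}

#' Pre/post window means around movement onsets
#'
#' For each cell, compares the trace mean over `[-win_s, 0)` against
#' `[0, win_s)` around each movement-onset trigger with a paired t-test
#' across triggers (zero-variance differences give `p = 1`). When the
#' triggers carry direction labels the analysis is run per direction.
#'
#' @param tm a [trace_matrix()].
#' @param triggers movement onset times (numeric vector), or a tibble with
#'   columns `t_start` and `kind` (e.g. [detect_turns()] output).
#' @param win_s window length on each side (default 1 s).
#' @param alpha significance level (default 0.05).
#' @return A tibble with columns `direction`, `cell_id`, `mean_pre`,
#'   `mean_post`, `p_value`, `significant`, `n_triggers`; zero usable
#'   triggers yield zero rows.
#' @export
action_window_means <- function(tm, triggers, win_s = 1, alpha = 0.05) {
  stopifnot(inherits(tm, "trace_matrix"))
  trig <- if (is.data.frame(triggers)) {
    tibble(t = triggers$t_start,
           direction = triggers$kind %||% "all")
  } else {
    tibble(t = as.numeric(triggers), direction = "all")
  }
  trig <- trig[trig$t - win_s >= min(tm$t) & trig$t + win_s <= max(tm$t), ]
  if (nrow(trig) == 0L) {
    return(tibble(direction = character(0), cell_id = character(0),
                  mean_pre = numeric(0), mean_post = numeric(0),
                  p_value = numeric(0), significant = logical(0),
                  n_triggers = integer(0)))
  }
  purrr::map_dfr(split(trig, trig$direction), function(tr) {
    purrr::map_dfr(seq_len(nrow(tm$values)), function(i) {
      v <- tm$values[i, ]
      pre <- vapply(tr$t, function(tt) {
        mean(v[tm$t >= tt - win_s & tm$t < tt])
      }, numeric(1))
      post <- vapply(tr$t, function(tt) {
        mean(v[tm$t >= tt & tm$t < tt + win_s])
      }, numeric(1))
      diffs <- post - pre
      p <- if (length(diffs) < 2L || sd(diffs) == 0 || !is.finite(sd(diffs))) {
        1
      } else {
        t.test(post, pre, paired = TRUE)$p.value
      }
      tibble(direction = tr$direction[1], cell_id = tm$cells$cell_id[i],
             mean_pre = mean(pre), mean_post = mean(post), p_value = p,
             significant = p < alpha, n_triggers = nrow(tr))
    })
  })
}
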