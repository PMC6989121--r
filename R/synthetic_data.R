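# Synthetic two-region session generator. Emits a complete session --
# event-driven fluorescence traces, IMU record, stimulation log -- plus the
# ground truth used by every recovery test: true onsets, planted ensemble
# membership, synchronous-event times, movement/rearing/turn intervals and
# per-cell stimulus-response classes.

#' Synthetic session configuration
#'
#' Defaults encode the statistics of dual-region (cerebellum + cortex)
#' recordings: Purkinje-dendrite event rates of 0.62 Hz vs 0.22 Hz in cortex,
#' GCaMP6f half-decay times of 0.217 s (CBL) and 0.488 s (CTX), 30 Hz frames,
#' a 104 Hz IMU, rearing bouts of 2.2 s at 1.47/min, and movement following a
#' synchronous pattern with ~80 ms latency.
#'
#' @param n_cells named integer vector, cells per region.
#' @param baseline_rate_hz named per-region baseline calcium-event rate.
#' @param t_half_s named per-region transient half-decay time (seconds).
#' @param rise_tau_s transient rise time constant (seconds).
#' @param amplitude transient peak amplitude (fluorescence a.u.).
#' @param noise_sd trace additive Gaussian noise SD (a.u.).
#' @param duration_s session length (seconds).
#' @param frame_rate_hz imaging rate.
#' @param accel_rate_hz IMU rate.
#' @param sp_rate_hz rate of planted global synchronous events.
#' @param sp_count exact number of planted synchronous events; overrides the
#'   Poisson draw from `sp_rate_hz` when non-`NULL` (used to plant ensembles
#'   firing a controlled number of times).
#' @param sp_ensemble_fraction named per-region fraction of cells belonging
#'   to the planted synchronous ensemble.
#' @param sp_jitter_sd_s Gaussian jitter SD of member onsets around each
#'   planted synchronous time.
#' @param sp_margin_s planted synchronous times are kept this far from the
#'   session edges so triggered windows fit.
#' @param p_move_given_sp probability that a movement bout follows a planted
#'   synchronous event.
#' @param move_latency_mean_s,move_latency_sd_s lognormal latency from
#'   synchronous event to movement-bout onset.
#' @param move_amp_g,move_duration_s movement bout half-sine amplitude (g)
#'   and duration.
#' @param accel_noise_g IMU per-channel Gaussian noise SD (g).
#' @param rearing_rate_per_min,rearing_duration_s,rearing_amp_g rearing
#'   template rate, duration and y-channel amplitude.
#' @param turn_rate_per_min,turn_duration_s,turn_amp_g turning template rate,
#'   duration and signed x-channel amplitude.
#' @param n_stim number of stimulation trials (0 disables stimulation).
#' @param stim_start_s,stim_interval_s,stim_duration_s stimulation schedule.
#' @param stim_site stimulation site label.
#' @param stim_class_probs named probabilities over per-cell response classes
#'   `increased`, `unchanged`, `decreased`.
#' @param stim_onset_latency_s,stim_onset_latency_sd_s response-onset latency
#'   (relative to stimulus offset) for `increased` cells.
#' @param stim_rate_boost_hz extra event rate of `increased` cells during
#'   long stimulation windows.
#' @param stim_suppression fraction of baseline events removed from
#'   `decreased` cells during stimulation.
#' @param seed integer; together with the other fields it fully determines
#'   the emitted session.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cells = c(CBL = 15L, CTX = 15L),
                         baseline_rate_hz = c(CBL = 0.62, CTX = 0.22),
                         t_half_s = c(CBL = 0.217, CTX = 0.488),
                         rise_tau_s = 0.02,
                         amplitude = 1,
                         noise_sd = 0.05,
                         duration_s = 300,
                         frame_rate_hz = 30,
                         accel_rate_hz = 104,
                         sp_rate_hz = 0.05,
                         sp_count = NULL,
                         sp_ensemble_fraction = c(CBL = 0.4, CTX = 0.4),
                         sp_jitter_sd_s = 0.025,
                         sp_margin_s = 5,
                         p_move_given_sp = 0.31,
                         move_latency_mean_s = 0.08,
                         move_latency_sd_s = 0.02,
                         move_amp_g = 0.3,
                         move_duration_s = 0.4,
                         accel_noise_g = 0.02,
                         rearing_rate_per_min = 0,
                         rearing_duration_s = 2.2,
                         rearing_amp_g = 0.35,
                         turn_rate_per_min = 0,
                         turn_duration_s = 0.5,
                         turn_amp_g = 0.3,
                         n_stim = 0L,
                         stim_start_s = 10,
                         stim_interval_s = 10,
                         stim_duration_s = 0.05,
                         stim_site = "site1",
                         stim_class_probs = c(increased = 1, unchanged = 0,
                                              decreased = 0),
                         stim_onset_latency_s = 0.22,
                         stim_onset_latency_sd_s = 0.05,
                         stim_rate_boost_hz = 1.4,
                         stim_suppression = 0.8,
                         seed = 1L) {
  cfg <- as.list(environment())
  regions <- names(cfg$n_cells)
  if (is.null(regions)) abort("n_cells must be a named vector of regions")
  for (f in c("baseline_rate_hz", "t_half_s", "sp_ensemble_fraction")) {
    if (!all(regions %in% names(cfg[[f]]))) {
      abort(sprintf("%s must name every region in n_cells", f))
    }
  }
  rates <- c(cfg$baseline_rate_hz, cfg$sp_rate_hz, cfg$rearing_rate_per_min,
             cfg$turn_rate_per_min)
  if (any(rates < 0)) abort("rates must be non-negative")
  fr <- c(cfg$sp_ensemble_fraction, cfg$p_move_given_sp, cfg$stim_class_probs,
          cfg$stim_suppression)
  if (any(fr < 0 | fr > 1)) abort("fractions/probabilities must lie in [0, 1]")
  structure(cfg, class = "synth_config")
}

.kernel_cache <- new.env(parent = emptyenv())

# peak time of (1 - exp(-t/tau)) * exp(-lam t): exp(-t/tau) = lam tau/(1+lam tau)
kernel_peak_time <- function(rise_tau_s, lam) {
  rise_tau_s * log((1 + lam * rise_tau_s) / (lam * rise_tau_s))
}

# decay rate such that the time from the kernel's peak to half its peak
# equals t_half_s; cached per (rise, t_half) pair. Half-decay times are
# measured from recordings as peak-to-half intervals, so the generator is
# calibrated to emit transients with exactly that measured statistic (for
# rise_tau -> 0 this reduces to lam = ln2 / t_half).
kernel_decay_rate <- function(rise_tau_s, t_half_s) {
  key <- sprintf("%.12g|%.12g", rise_tau_s, t_half_s)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  k0 <- function(t, lam) (1 - exp(-t / rise_tau_s)) * exp(-lam * t)
  half_from_peak <- function(lam) {
    tp <- kernel_peak_time(rise_tau_s, lam)
    pk <- k0(tp, lam)
    stats::uniroot(function(d) k0(tp + d, lam) - pk / 2,
                   c(1e-12, 100 * t_half_s), tol = 1e-12)$root
  }
  lam0 <- log(2) / t_half_s
  lam <- tryCatch(
    stats::uniroot(function(l) half_from_peak(l) - t_half_s,
                   c(lam0 / 10, lam0 * 10), tol = 1e-12)$root,
    error = function(e) lam0
  )
  .kernel_cache[[key]] <- lam
  lam
}

#' Calcium transient kernel
#'
#' Double-exponential (rise x decay) transient shape,
#' `k(t) = (1 - exp(-t / rise_tau)) * exp(-lambda t)` for `t >= 0` and 0
#' before, normalized to unit peak. The decay rate `lambda` is calibrated so
#' that the time from the kernel's peak to half its peak equals `t_half_s` --
#' the half-decay statistic actually measured from recordings (for a
#' vanishing rise this is exactly `lambda = ln2 / t_half_s`).
#'
#' @param t numeric vector of times (seconds).
#' @param rise_tau_s rise time constant, > 0.
#' @param t_half_s peak-to-half decay time, > 0.
#' @return kernel values, unit peak.
#' @export
gcamp_kernel <- function(t, rise_tau_s, t_half_s) {
  if (rise_tau_s <= 0 || t_half_s <= 0) {
    abort("rise_tau_s and t_half_s must be positive")
  }
  lam <- kernel_decay_rate(rise_tau_s, t_half_s)
  k <- ifelse(t >= 0, (1 - exp(-t / rise_tau_s)) * exp(-lam * t), 0)
  t_peak <- kernel_peak_time(rise_tau_s, lam)
  peak <- (1 - exp(-t_peak / rise_tau_s)) * exp(-lam * t_peak)
  k / peak
}

# render one cell's trace from its onset times
render_trace <- function(onsets, t, rise_tau_s, t_half_s, amplitude) {
  out <- numeric(length(t))
  if (length(onsets) == 0L) return(out)
  dt <- if (length(t) > 1L) t[2] - t[1] else 1
  support <- 8 * t_half_s + 5 * rise_tau_s
  for (on in onsets) {
    i0 <- max(1L, ceiling((on - t[1]) / dt))
    i1 <- min(length(t), ceiling((on + support - t[1]) / dt))
    if (i1 < i0) next
    idx <- i0:i1
    out[idx] <- out[idx] +
      amplitude * gcamp_kernel(t[idx] - on, rise_tau_s, t_half_s)
  }
  out
}

# half-sine envelope template, 0 outside [0, dur]
half_sine <- function(t, dur) ifelse(t >= 0 & t <= dur, sin(pi * t / dur), 0)

# rise-plateau-fall rearing template (25/50/25 split), unit peak
trapezoid <- function(t, dur) {
  r <- dur * 0.25
  up <- pmin(pmax(t / r, 0), 1)
  down <- pmin(pmax((dur - t) / r, 0), 1)
  ifelse(t >= 0 & t <= dur, pmin(up, down), 0)
}

# sequentially place n template starts in [lo, hi] with min separation;
# draws that collide are rejected (truth records what was kept)
place_starts <- function(n, lo, hi, min_sep) {
  if (n <= 0L || hi <= lo) return(numeric(0))
  starts <- numeric(0)
  for (s in sort(runif(n, lo, hi))) {
    if (all(abs(s - starts) >= min_sep)) starts <- c(starts, s)
  }
  starts
}

#' Simulate a complete session
#'
#' Baseline events per cell follow a homogeneous Poisson process; planted
#' synchronous events inject one jittered onset into every ensemble member;
#' traces are the onset trains convolved with [gcamp_kernel()] plus Gaussian
#' noise; the IMU record carries Gaussian noise plus movement bouts coupled
#' to the synchronous events, rearing templates on y/z and signed turn pulses
#' on x; stimulation trials perturb cells according to their planted response
#' class. Identical `config` (including `seed`) gives identical output.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_session` with elements `traces`
#'   ([trace_matrix()]), `accel` ([accel_record()]), `stim` ([stim_log()] or
#'   `NULL`), and `truth` (ground-truth list: `onsets`, `ensemble`,
#'   `sp_times`, `movements`, `rearings`, `turns`, `stim_classes`, `config`).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  regions <- names(cfg$n_cells)
  dur <- cfg$duration_s

  cells <- dplyr::bind_rows(lapply(regions, function(r) {
    n <- cfg$n_cells[[r]]
    tibble(cell_id = sprintf("%s_%03d", r, seq_len(n)), region = r)
  }))

  # --- baseline events -------------------------------------------------
  base_onsets <- with_seed(derive_seed(cfg$seed, "events"), {
    purrr::map2(cells$cell_id, cells$region, function(id, r) {
      n <- rpois(1L, cfg$baseline_rate_hz[[r]] * dur)
      sort(runif(n, 0, dur))
    })
  })
  names(base_onsets) <- cells$cell_id

  # --- planted ensemble + synchronous times ----------------------------
  ens <- with_seed(derive_seed(cfg$seed, "ensemble"), {
    members <- unlist(lapply(regions, function(r) {
      ids <- cells$cell_id[cells$region == r]
      k <- round(cfg$sp_ensemble_fraction[[r]] * length(ids))
      if (k > 0) sample(ids, k) else character(0)
    }))
    lo <- min(cfg$sp_margin_s, dur / 2)
    hi <- max(dur - cfg$sp_margin_s, lo)
    n_sp <- if (is.null(cfg$sp_count)) {
      rpois(1L, cfg$sp_rate_hz * dur)
    } else {
      as.integer(cfg$sp_count)
    }
    list(members = members, sp_times = sort(runif(n_sp, lo, hi)))
  })

  sp_onsets <- with_seed(derive_seed(cfg$seed, "jitter"), {
    lapply(setNames(nm = ens$members), function(id) {
      if (length(ens$sp_times) == 0L) return(numeric(0))
      pmin(pmax(ens$sp_times + rnorm(length(ens$sp_times),
                                     sd = cfg$sp_jitter_sd_s), 0), dur)
    })
  })

  # --- stimulation trials ----------------------------------------------
  stim <- NULL
  stim_classes <- tibble(cell_id = character(0), class = character(0))
  stim_extra <- list()
  if (cfg$n_stim > 0L) {
    onsets <- cfg$stim_start_s + cfg$stim_interval_s * (seq_len(cfg$n_stim) - 1)
    if (max(onsets) + cfg$stim_duration_s + 2 > dur) {
      abort("duration_s too short for the requested stimulation schedule")
    }
    stim <- stim_log(onsets, cfg$stim_duration_s, site = cfg$stim_site)
    offs <- onsets + cfg$stim_duration_s
    p <- cfg$stim_class_probs / sum(cfg$stim_class_probs)
    res <- with_seed(derive_seed(cfg$seed, "stim"), {
      cls <- sample(names(p), nrow(cells), replace = TRUE, prob = p)
      extra <- lapply(seq_len(nrow(cells)), function(i) {
        id <- cells$cell_id[i]
        if (cls[i] == "increased") {
          evoked <- offs + pmax(rnorm(length(offs), cfg$stim_onset_latency_s,
                                      cfg$stim_onset_latency_sd_s), 0.01)
          burst <- unlist(lapply(onsets, function(on) {
            w <- cfg$stim_duration_s
            if (w < 1) return(numeric(0))
            nb <- rpois(1L, cfg$stim_rate_boost_hz * w)
            sort(runif(nb, on + 0.2, on + w))
          }))
          sort(c(evoked, burst))
        } else if (cls[i] == "decreased") {
          keep <- base_onsets[[id]]
          in_win <- vapply(keep, function(x) {
            any(x >= onsets & x < onsets + cfg$stim_duration_s)
          }, logical(1))
          drop <- in_win & (runif(length(keep)) < cfg$stim_suppression)
          base_onsets[[id]] <<- keep[!drop]
          numeric(0)
        } else numeric(0)
      })
      list(cls = cls, extra = extra)
    })
    stim_classes <- tibble(cell_id = cells$cell_id, class = res$cls)
    stim_extra <- setNames(res$extra, cells$cell_id)
  }

  # --- merge onset sources ---------------------------------------------
  all_onsets <- lapply(setNames(nm = cells$cell_id), function(id) {
    sort(c(base_onsets[[id]], sp_onsets[[id]] %||% numeric(0),
           stim_extra[[id]] %||% numeric(0)))
  })
  truth_onsets <- dplyr::bind_rows(purrr::imap(all_onsets, function(on, id) {
    tibble(cell_id = id, onset_s = on)
  }))
  truth_onsets <- dplyr::left_join(truth_onsets, cells, by = "cell_id")

  # --- traces -----------------------------------------------------------
  frame_t <- seq(0, dur - 1e-9, by = 1 / cfg$frame_rate_hz)
  vals <- t(vapply(seq_len(nrow(cells)), function(i) {
    r <- cells$region[i]
    render_trace(all_onsets[[cells$cell_id[i]]], frame_t,
                 cfg$rise_tau_s, cfg$t_half_s[[r]], cfg$amplitude)
  }, numeric(length(frame_t))))
  if (cfg$noise_sd > 0) {
    vals <- vals + with_seed(derive_seed(cfg$seed, "trace_noise"), {
      matrix(rnorm(length(vals), sd = cfg$noise_sd), nrow = nrow(vals))
    })
  }
  traces <- trace_matrix(vals, frame_t, cells$cell_id, cells$region,
                         frame_rate_hz = cfg$frame_rate_hz)

  # --- accelerometer ----------------------------------------------------
  acc_t <- seq(0, dur - 1e-9, by = 1 / cfg$accel_rate_hz)
  acc <- with_seed(derive_seed(cfg$seed, "accel_noise"), {
    matrix(rnorm(3L * length(acc_t), sd = cfg$accel_noise_g), ncol = 3L)
  })

  movements <- tibble(t0 = numeric(0), t1 = numeric(0), sp_time = numeric(0))
  if (length(ens$sp_times) > 0L && cfg$p_move_given_sp > 0) {
    mv <- with_seed(derive_seed(cfg$seed, "movement"), {
      go <- runif(length(ens$sp_times)) < cfg$p_move_given_sp
      lat <- rlnorm_ms(sum(go), cfg$move_latency_mean_s, cfg$move_latency_sd_s)
      dirs <- matrix(rnorm(3L * sum(go)), ncol = 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(go = go, lat = lat, dirs = dirs)
    })
    starts <- ens$sp_times[mv$go] + mv$lat
    for (j in seq_along(starts)) {
      env <- cfg$move_amp_g * half_sine(acc_t - starts[j], cfg$move_duration_s)
      acc <- acc + outer(env, mv$dirs[j, ])
    }
    movements <- tibble(t0 = starts, t1 = starts + cfg$move_duration_s,
                        sp_time = ens$sp_times[mv$go])
  }

  rearings <- tibble(t0 = numeric(0), t1 = numeric(0))
  if (cfg$rearing_rate_per_min > 0) {
    starts <- with_seed(derive_seed(cfg$seed, "rearing"), {
      n <- rpois(1L, cfg$rearing_rate_per_min * dur / 60)
      place_starts(n, 1, dur - cfg$rearing_duration_s - 1,
                   2 * cfg$rearing_duration_s)
    })
    for (s in starts) {
      shape <- trapezoid(acc_t - s, cfg$rearing_duration_s)
      acc[, 2] <- acc[, 2] + cfg$rearing_amp_g * shape
      acc[, 3] <- acc[, 3] + 0.5 * cfg$rearing_amp_g * shape
    }
    rearings <- tibble(t0 = starts, t1 = starts + cfg$rearing_duration_s)
  }

  turns <- tibble(t0 = numeric(0), t1 = numeric(0), direction = character(0))
  if (cfg$turn_rate_per_min > 0) {
    tu <- with_seed(derive_seed(cfg$seed, "turning"), {
      n <- rpois(1L, cfg$turn_rate_per_min * dur / 60)
      starts <- place_starts(n, 1, dur - cfg$turn_duration_s - 1,
                             3 * cfg$turn_duration_s)
      list(starts = starts,
           sign = sample(c(-1, 1), length(starts), replace = TRUE))
    })
    for (j in seq_along(tu$starts)) {
      acc[, 1] <- acc[, 1] + tu$sign[j] * cfg$turn_amp_g *
        half_sine(acc_t - tu$starts[j], cfg$turn_duration_s)
    }
    turns <- tibble(t0 = tu$starts, t1 = tu$starts + cfg$turn_duration_s,
                    direction = ifelse(tu$sign > 0, "turn_left", "turn_right"))
  }

  accel <- accel_record(acc_t, acc[, 1], acc[, 2], acc[, 3],
                        nominal_rate_hz = cfg$accel_rate_hz)

  truth <- list(
    onsets = truth_onsets[c("cell_id", "region", "onset_s")],
    ensemble = dplyr::mutate(cells,
                             is_member = .data$cell_id %in% ens$members),
    sp_times = ens$sp_times,
    movements = movements,
    rearings = rearings,
    turns = turns,
    stim_classes = stim_classes,
    config = cfg
  )
  structure(list(traces = traces, accel = accel, stim = stim, truth = truth),
            class = "synth_session")
}

# lognormal draws parameterized by the target mean and sd of the latency
rlnorm_ms <- function(n, mean_s, sd_s) {
  if (n == 0L) return(numeric(0))
  cv2 <- (sd_s / mean_s)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean_s) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

#' Write a synthetic session to a directory
#'
#' Emits the four CSV artifacts (`traces.csv`, `accel.csv`, `stim.csv`,
#' `events_truth.csv`) plus `truth.json` with the remaining ground truth.
#'
#' @param session a `synth_session`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synth_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trace_table(session$traces, file.path(dir, "traces.csv"))
  write_accel_table(session$accel, file.path(dir, "accel.csv"))
  if (!is.null(session$stim)) {
    write_stim_table(session$stim, file.path(dir, "stim.csv"))
  }
  readr::write_csv(session$truth$onsets, file.path(dir, "events_truth.csv"),
                   progress = FALSE)
  truth <- session$truth
  truth$onsets <- NULL
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
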