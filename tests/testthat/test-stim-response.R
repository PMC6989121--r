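# session with stimulation trials and planted per-cell response classes
stim_session <- function(seed, probs = c(increased = 0.5, unchanged = 0.5,
                                         decreased = 0),
                         n_stim = 10L, stim_duration_s = 0.05,
                         baseline_rate = 0.22, stim_interval_s = 10, ...) {
  simulate_session(synth_config(
    n_cells = c(CTX = 20L),
    baseline_rate_hz = c(CTX = baseline_rate),
    t_half_s = c(CTX = 0.488),
    sp_ensemble_fraction = c(CTX = 0),
    sp_rate_hz = 0, p_move_given_sp = 0,
    duration_s = 20 + n_stim * stim_interval_s, n_stim = n_stim,
    stim_start_s = 10, stim_interval_s = stim_interval_s,
    stim_duration_s = stim_duration_s,
    stim_class_probs = probs, seed = seed, ...
  ))
}

test_that("trial construction drops edge trials and aligns to onset or offset", {
  s <- stim_session(seed = 1L)
  tt <- build_trials(s$traces, s$stim, pre_s = 2, post_s = 3)
  expect_identical(dim(tt$data)[2], 10L)
  expect_identical(tt$n_dropped, 0L)

  # a stimulus too close to the recording start is dropped and counted
  early <- stim_log(c(0.5, s$stim$onset_s), 0.05)
  tt2 <- build_trials(s$traces, early, pre_s = 2, post_s = 3)
  expect_identical(tt2$n_dropped, 1L)
  expect_identical(dim(tt2$data)[2], 10L)

  # offset alignment shifts the sampling times by exactly the stimulus
  # duration: each snippet equals the trace interpolated at offset + rel_t
  off <- build_trials(s$traces, s$stim, pre_s = 2, post_s = 3,
                      align = "offset")
  i <- match("CTX_001", off$cells$cell_id)
  dur <- s$stim$duration_s[1]
  expect_equal(
    off$data[i, 1, ],
    approx(s$traces$t, s$traces$values[i, ],
           xout = s$stim$onset_s[1] + dur + off$rel_t, rule = 2)$y,
    tolerance = 1e-9
  )
})

test_that("responder calls follow the mean + 2 sigma rule with degenerate sigma", {
  t <- seq(0, 100, by = 1 / 30)
  flat <- matrix(1, nrow = 2, ncol = length(t))
  # second cell carries a clear post-stimulus deflection
  stim <- stim_log(c(20, 40, 60), 0.05)
  for (on in stim$onset_s) flat[2, t >= on + 0.2 & t <= on + 0.8] <- 2
  tm <- trace_matrix(flat, t, cell_ids = c("quiet", "active"),
                     region = "CTX")
  tt <- build_trials(tm, stim, pre_s = 2, post_s = 3)
  res <- classify_responders(tt, fit_onset = FALSE)
  # flat cell is no responder; with sigma = 0 the threshold degenerates to
  # the baseline mean, so any positive deflection responds
  expect_identical(res$calls$is_responder, c(FALSE, TRUE))
  expect_equal(res$responder_fraction, 0.5)
})

test_that("responders are invariant to affine rescaling of a cell's trace", {
  s <- stim_session(seed = 2L)
  tt <- build_trials(s$traces, s$stim, pre_s = 2, post_s = 3)
  r1 <- classify_responders(tt, fit_onset = FALSE)$calls
  tt2 <- tt
  tt2$data <- tt2$data * 3.7 + 11
  r2 <- classify_responders(tt2, fit_onset = FALSE)$calls
  expect_identical(r1$is_responder, r2$is_responder)
})

test_that("planted responders are called with high sensitivity and specificity", {
  res <- vapply(1:5, function(seed) {
    s <- stim_session(seed = seed)
    tt <- build_trials(s$traces, s$stim, pre_s = 2, post_s = 3)
    calls <- classify_responders(tt, fit_onset = FALSE)$calls
    truth <- s$truth$stim_classes
    joined <- merge(calls, truth, by = "cell_id")
    pos <- joined$class == "increased"
    c(sens = mean(joined$is_responder[pos]),
      spec = mean(!joined$is_responder[!pos]))
  }, numeric(2))
  expect_gte(mean(res["sens", ]), 0.95)
  expect_gte(mean(res["spec", ]), 0.95)
})

test_that("sigmoid onset inverts noiseless logistics and handles steps", {
  t <- seq(0, 3, by = 1 / 30)
  b <- 0.5; A <- 2; t0 <- 1.2; sl <- 0.12
  v <- b + A / (1 + exp(-(t - t0) / sl))
  fit <- sigmoid_onset(t, v, baseline_mean = b, baseline_sd = 0.1)
  expect_identical(fit$flag, "fit")
  # analytic crossing of b + sd on the true curve
  thr <- b + 0.1
  t_true <- t0 - sl * log(A / (thr - b) - 1)
  expect_lt(abs(fit$onset_s - t_true), 1 / 30)

  # step function: onset within one sample of the step
  vs <- ifelse(t >= 1.5, 2, 0)
  fs <- sigmoid_onset(t, vs, baseline_mean = 0, baseline_sd = 0.05)
  expect_lt(abs(fs$onset_s - 1.5), 1 / 30 + 1e-9)

  # onset error grows no worse than gracefully with noise
  set.seed(7)
  errs <- vapply(c(0.01, 0.1), function(ns) {
    med <- median(vapply(1:20, function(i) {
      fit <- sigmoid_onset(t, v + rnorm(length(t), sd = ns), b, 0.1)
      abs(fit$onset_s - t_true)
    }, numeric(1)))
    med
  }, numeric(1))
  expect_lte(errs[1], errs[2] + 1 / 30)
  expect_lt(errs[1], 1 / 30)
})

test_that("planted cortical onset latencies are recovered by the sigmoid fit", {
  s <- stim_session(seed = 11L, probs = c(increased = 1, unchanged = 0,
                                          decreased = 0))
  tt <- build_trials(s$traces, s$stim, pre_s = 2, post_s = 3)
  calls <- classify_responders(tt)$calls
  got <- calls[calls$is_responder & !is.na(calls$onset_s), ]
  expect_gt(nrow(got), 10)
  # planted onset: stimulus offset + 0.22 s mean latency; the fitted onset
  # marks the rise start, within about two frames
  err <- got$onset_s - (median(s$stim$duration_s) + 0.22)
  expect_lt(abs(median(err)), 2 / 30)
})

test_that("modulation classes follow the paired t-test with zero-variance p = 1", {
  t <- seq(0, 100, by = 1 / 30)
  stim <- stim_log(seq(20, 80, by = 10), 2)
  # identical pre and stim means in every trial -> unchanged with p = 1
  tm <- trace_matrix(matrix(1, 1, length(t)), t, "const", "DS")
  tt <- build_trials(tm, stim, pre_s = 2, post_s = 3)
  mod <- classify_modulation(tt)
  expect_identical(mod$calls$class, "unchanged")
  expect_identical(mod$calls$p_value, 1)
  expect_equal(sum(mod$fractions$fraction), 1)
})

test_that("planted DS modulation clusters are recovered with their event rates", {
  res <- vapply(1:5, function(seed) {
    s <- stim_session(seed = seed,
                      probs = c(increased = 0.2, unchanged = 0.5,
                                decreased = 0.3),
                      n_stim = 10L, stim_duration_s = 10,
                      stim_interval_s = 25, baseline_rate = 1.1,
                      stim_rate_boost_hz = 1.4, stim_suppression = 0.8)
    tt <- build_trials(s$traces, s$stim, pre_s = 5, post_s = 12)
    ev <- detect_events(s$traces, onset_params(t_half_s = 0.488))
    mod <- classify_modulation(tt, events = ev)
    joined <- merge(mod$calls, s$truth$stim_classes, by = "cell_id")
    c(dec = mean(joined$class.x[joined$class.y == "decreased"] == "decreased"),
      inc = mean(joined$class.x[joined$class.y == "increased"] == "increased"))
  }, numeric(2))
  expect_gte(mean(res["dec", ], na.rm = TRUE), 0.9)
  expect_gte(mean(res["inc", ], na.rm = TRUE), 0.9)
})

test_that("action-window means find contralateral-locked cells only", {
  # constructed: cell A responds after left turns, cell B never
  t <- seq(0, 200, by = 1 / 30)
  left <- seq(20, 180, by = 20)
  right <- seq(30, 190, by = 20)
  vA <- numeric(length(t))
  for (on in left) vA <- vA + gcamp_kernel(t - on - 0.3, 0.02, 0.488)
  set.seed(6)
  vA <- vA + rnorm(length(t), sd = 0.03)
  vB <- rnorm(length(t), sd = 0.03)
  tm <- trace_matrix(rbind(vA, vB), t, c("A", "B"), "DS")
  triggers <- tibble::tibble(
    t_start = c(left, right),
    kind = rep(c("turn_left", "turn_right"), c(length(left), length(right)))
  )
  res <- action_window_means(tm, triggers)
  sigA <- res[res$cell_id == "A", ]
  expect_true(sigA$significant[sigA$direction == "turn_left"])
  expect_false(sigA$significant[sigA$direction == "turn_right"])
  expect_false(any(res$significant[res$cell_id == "B"]))
  expect_gt(sigA$mean_post[sigA$direction == "turn_left"],
            sigA$mean_pre[sigA$direction == "turn_left"])

  # no triggers at all -> empty result
  expect_identical(nrow(action_window_means(tm, numeric(0))), 0L)
})
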