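# helpers to synthesize IMU records directly
noise_accel <- function(dur, sd = 0.02, rate = 104, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur, by = 1 / rate)
  accel_record(t, rnorm(length(t), sd = sd), rnorm(length(t), sd = sd),
               rnorm(length(t), sd = sd))
}

test_that("compound acceleration is the rotation-invariant vector norm", {
  # 3-4-5 triple scaled into the sensor range
  acc <- accel_record(t = 0:2, x = c(0.3, 0, 0.1), y = c(0.4, 0, 0.2),
                      z = c(0, 0, 0.2))
  a <- compound_accel(acc)
  expect_equal(a$a, c(0.5, 0, 0.3))

  # invariant under a random 3D rotation
  set.seed(2)
  m <- matrix(rnorm(9), 3)
  rot <- qr.Q(qr(m))
  v <- cbind(acc$x, acc$y, acc$z) %*% t(rot)
  a2 <- compound_accel(accel_record(acc$t, v[, 1], v[, 2], v[, 3]))
  expect_equal(a2$a, a$a, tolerance = 1e-12)
})

test_that("SP triggers on silent accelerometer classify as no change", {
  t <- seq(0, 60, by = 1 / 104)
  a <- tibble::tibble(t = t, a = numeric(length(t)))
  res <- classify_sp_triggers(a, sp_times = c(10, 20, 30))
  expect_true(all(res$classes$category == "no_change"))
  expect_equal(sum(res$fractions$fraction), 1)
})

test_that("bouts planted after the SP are classified post, within the band around", {
  t <- seq(0, 60, by = 1 / 104)
  bump <- function(center, dur = 0.2, amp = 0.5) {
    amp * ifelse(t >= center & t <= center + dur,
                 sin(pi * (t - center) / dur), 0)
  }
  # bounded (uniform) resting noise never exceeds its own mean + 2 sigma,
  # so the category is decided by where the planted bout falls; smoothing
  # is disabled to keep the bump's support exact
  set.seed(3)
  base <- runif(length(t), 0, 0.02)

  # clear movement 0.3 s after the SP -> post
  a_post <- tibble::tibble(t = t, a = base + bump(30.3))
  res <- classify_sp_triggers(a_post, sp_times = 30, lp_cutoff_hz = Inf)
  expect_identical(res$classes$category, "post")

  # movement confined to the central +/- 150 ms band -> around
  a_mid <- tibble::tibble(t = t, a = base + bump(30 - 0.1, dur = 0.2))
  res2 <- classify_sp_triggers(a_mid, sp_times = 30, lp_cutoff_hz = Inf)
  expect_identical(res2$classes$category, "around")

  # movement well before the SP -> pre
  a_pre <- tibble::tibble(t = t, a = base + bump(29.0))
  res3 <- classify_sp_triggers(a_pre, sp_times = 30, lp_cutoff_hz = Inf)
  expect_identical(res3$classes$category, "pre")

  # SP too close to the recording edge is dropped and counted
  res4 <- classify_sp_triggers(a_post, sp_times = c(0.5, 30),
                               lp_cutoff_hz = Inf)
  expect_identical(res4$n_dropped_edge, 1L)
  expect_identical(nrow(res4$classes), 1L)
})

test_that("coupled sessions classify most SPs as post and partition exactly", {
  hits <- vapply(1:3, function(seed) {
    # low planted-SP density: a Poisson SP within 2 s of another puts its
    # bout in the neighbor's pre-window, which is contamination of the
    # trigger, not a classifier error
    s <- simulate_session(synth_config(duration_s = 300, sp_rate_hz = 0.04,
                                       p_move_given_sp = 1, seed = seed))
    a <- compound_accel(s$accel)
    res <- classify_sp_triggers(a, s$truth$sp_times)
    expect_identical(sum(res$fractions$n) + res$n_dropped_edge,
                     length(s$truth$sp_times))
    f <- res$fractions
    c(f$n[f$category == "post"], sum(f$n))
  }, numeric(2))
  expect_gte(sum(hits[1, ]) / sum(hits[2, ]), 0.9)
})

test_that("random-trigger control flags coupled sessions but needs triggers", {
  s <- simulate_session(synth_config(duration_s = 300, sp_rate_hz = 0.1,
                                     p_move_given_sp = 1, seed = 12L))
  a <- compound_accel(s$accel)
  res <- random_trigger_null(a, s$truth$sp_times, n_triggers = 100L,
                             seed = 1L)
  expect_gt(res$frac_sp, res$frac_random)
  expect_lt(res$p_value, 0.05)
  expect_error(random_trigger_null(a, s$truth$sp_times, n_triggers = 0L),
               "n_triggers")
})

test_that("planted rearings are segmented with accurate durations and rate", {
  s <- simulate_session(synth_config(
    duration_s = 600, sp_rate_hz = 0, p_move_given_sp = 0,
    rearing_rate_per_min = 1.47, seed = 6L
  ))
  truth <- s$truth$rearings
  res <- detect_rearings(s$accel)
  expect_gte(match_epochs(res$epochs, truth), 0.9)
  expect_lt(abs(res$stats$mean_duration_s - 2.2), 0.3)
  expect_lt(abs(res$stats$rate_per_min - nrow(truth) / 10), 0.3)

  # flat channel -> nothing
  flat <- detect_rearings(noise_accel(60, sd = 0))
  expect_identical(nrow(flat$epochs), 0L)
  expect_identical(flat$stats$rate_per_min, 0)
})

test_that("rearing epochs equal a brute-force hysteresis scan", {
  s <- simulate_session(synth_config(
    duration_s = 240, sp_rate_hz = 0, p_move_given_sp = 0,
    rearing_rate_per_min = 2, seed = 7L
  ))
  rate <- 1 / median(diff(s$accel$t))
  y <- as.numeric(signal::filtfilt(signal::butter(2, 2 / (rate / 2), "low"),
                                   s$accel$y))
  oracle <- brute_hysteresis(s$accel$t, y, 0.15, 0.08)
  res <- detect_rearings(s$accel)
  # same excursions found; each detected epoch contains its oracle core
  # (bounds are extended outward to the low edge threshold)
  expect_identical(nrow(res$epochs), length(oracle))
  if (length(oracle) > 0) {
    expect_true(all(res$epochs$t_start <=
                      vapply(oracle, `[`, numeric(1), 1) + 1e-9))
    expect_true(all(res$epochs$t_end >=
                      vapply(oracle, `[`, numeric(1), 2) - 1e-9))
    expect_true(all(vapply(oracle, `[`, numeric(1), 1) -
                      res$epochs$t_start < 0.6))
  }
})

test_that("turns are detected with correct lateralization and sign symmetry", {
  # constructed alternating pulses
  t <- seq(0, 120, by = 1 / 104)
  x <- numeric(length(t))
  centers <- seq(10, 110, by = 10)
  signs <- rep(c(1, -1), length.out = length(centers))
  for (i in seq_along(centers)) {
    sel <- t >= centers[i] & t <= centers[i] + 0.5
    x[sel] <- x[sel] + signs[i] * 0.4 * sin(pi * (t[sel] - centers[i]) / 0.5)
  }
  acc <- accel_record(t, x, numeric(length(t)), numeric(length(t)))
  ep <- detect_turns(acc)
  expect_identical(nrow(ep), length(centers))
  expect_identical(ep$kind, ifelse(signs > 0, "turn_left", "turn_right"))

  # flipping the sign convention swaps every label
  ep2 <- detect_turns(acc, positive_is_left = FALSE)
  expect_identical(ep2$kind, ifelse(signs > 0, "turn_right", "turn_left"))

  # silent x channel -> no turns
  expect_identical(nrow(detect_turns(noise_accel(60, sd = 0))), 0L)

  # generator turns are recovered
  s <- simulate_session(synth_config(duration_s = 300, sp_rate_hz = 0,
                                     p_move_given_sp = 0,
                                     turn_rate_per_min = 2, seed = 9L))
  det <- detect_turns(s$accel)
  truth <- s$truth$turns
  expect_gte(match_epochs(det, truth), 0.9)
  hit_dir <- vapply(seq_len(nrow(truth)), function(i) {
    mid <- (truth$t0[i] + truth$t1[i]) / 2
    j <- which(det$t_start - 0.5 <= mid & det$t_end + 0.5 >= mid)[1]
    !is.na(j) && det$kind[j] == truth$direction[i]
  }, logical(1))
  expect_gte(mean(hit_dir), 0.9)
})

test_that("triggered averages have correct mean, SEM and latency behavior", {
  t <- seq(0, 100, by = 1 / 104)
  set.seed(13)
  v <- rnorm(length(t))

  # a single trigger returns the snippet itself with zero SEM
  one <- event_triggered_average(t, v, 50, win_s = 1)
  expect_identical(one$n_triggers, 1L)
  expect_true(all(one$sem == 0))
  expect_equal(one$mean, approx(t, v, 50 + one$rel_t)$y)

  # many triggers on white noise: mean -> 0, SEM -> sigma / sqrt(n)
  trig <- seq(5, 95, by = 1)
  eta <- event_triggered_average(t, v, trig, win_s = 1)
  expect_lt(max(abs(eta$mean)), 5 / sqrt(length(trig)))
  expect_equal(mean(eta$sem), 1 / sqrt(length(trig)), tolerance = 0.2)

  # planted bout latency is recovered in the compound signal
  s <- simulate_session(synth_config(duration_s = 300, sp_rate_hz = 0.1,
                                     p_move_given_sp = 1,
                                     accel_noise_g = 0.005, seed = 10L))
  a <- compound_accel(s$accel)
  eta2 <- event_triggered_average(a$t, a$a, s$truth$sp_times, win_s = 2)
  # bout peak sits at latency + half the bout duration
  expected_peak <- 0.08 + 0.2
  expect_lt(abs(eta2$peak_latency_s - expected_peak), 0.1)

  expect_error(event_triggered_average(t, v, 1000, win_s = 1), "window")
})
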