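test_that("Epanechnikov kernel matches its closed form and integral", {
  h <- 0.1
  expect_identical(epanechnikov(0, h), 1)
  expect_identical(epanechnikov(c(-h, h), h), c(0, 0))
  expect_equal(epanechnikov(h / 2, h), 0.75)
  expect_identical(epanechnikov(c(-1, 1), h), c(0, 0))
  # integral = 4h/3 by quadrature
  igr <- stats::integrate(epanechnikov, -h, h, h_s = h, rel.tol = 1e-10)
  expect_equal(igr$value, 4 * h / 3, tolerance = 1e-8)
})

test_that("kernel sum superposes onsets and matches the brute-force oracle", {
  one <- tibble::tibble(cell_id = "a", onset_s = 5)
  ks <- kernel_sum(one, h_s = 0.1, dt_s = 0.01, duration_s = 10)
  expect_equal(max(ks$S), 1, tolerance = 1e-12)
  expect_equal(ks$t[which.max(ks$S)], 5)
  expect_true(all(ks$S >= 0))

  two <- tibble::tibble(cell_id = c("a", "b"), onset_s = c(5, 5))
  ks2 <- kernel_sum(two, h_s = 0.1, dt_s = 0.01, duration_s = 10)
  expect_equal(max(ks2$S), 2, tolerance = 1e-12)

  set.seed(11)
  ev <- tibble::tibble(
    cell_id = sample(letters[1:10], 100, replace = TRUE),
    onset_s = runif(100, 0, 60)
  )
  ks3 <- kernel_sum(ev, h_s = 0.1, dt_s = 0.02, duration_s = 60)
  expect_equal(ks3$S, brute_kernel_sum(ev$onset_s, ks3$t, 0.1),
               tolerance = 1e-9)
  expect_equal(ks3$threshold, mean(ks3$S) + 2 * sd(ks3$S), tolerance = 1e-12)

  expect_error(kernel_sum(ev[0, ]), "at least one event")
  expect_error(kernel_sum(ev, h_s = 0.1, dt_s = 0.05), "dt_s")
})

test_that("sync events are maximal supra-threshold runs with half-open membership", {
  # hand-built series: two runs above threshold
  grid <- seq(0, 1, by = 0.01)
  S <- numeric(length(grid))
  S[grid >= 0.20 & grid <= 0.25] <- 5
  S[grid >= 0.60 & grid <= 0.62] <- 5
  ks <- structure(list(t = grid, S = S, mu = 0.2, sigma = 0.4,
                       threshold = 1, h_s = 0.1, dt_s = 0.01),
                  class = "kernel_sum")
  ev <- tibble::tibble(
    cell_id = c("a", "b", "c", "d"),
    # c sits exactly at the first interval's t1 -> excluded (half-open);
    # d lies in the second interval
    onset_s = c(0.21, 0.24, 0.26, 0.61)
  )
  se <- detect_sync_events(ks, ev)
  expect_identical(nrow(se), 2L)
  expect_equal(se$t0, c(0.20, 0.60))
  expect_equal(se$t1, c(0.25 + 0.01, 0.62 + 0.01))
  expect_setequal(se$participants[[1]], c("a", "b"))
  # onset exactly at t1 of a shifted interval is not a participant
  ks$S[grid >= 0.20 & grid <= 0.25] <- 5
  ev2 <- dplyr::bind_rows(ev, tibble::tibble(cell_id = "e", onset_s = 0.26))
  se2 <- detect_sync_events(ks, ev2)
  expect_false("e" %in% se2$participants[[1]])

  # flat series: no events
  ks0 <- structure(list(t = grid, S = numeric(length(grid)), mu = 0,
                        sigma = 0, threshold = 0.5, h_s = 0.1, dt_s = 0.01),
                   class = "kernel_sum")
  expect_identical(nrow(detect_sync_events(ks0, ev)), 0L)
})

test_that("pair counting applies the >= 5 rule at its boundary", {
  mk_events <- function(n_shared) {
    tibble::tibble(
      event_id = seq_len(n_shared),
      t0 = seq_len(n_shared) * 10,
      t1 = seq_len(n_shared) * 10 + 0.2,
      n_participants = 2L,
      participants = replicate(n_shared, c("a", "b"), simplify = FALSE)
    )
  }
  cells <- tibble::tibble(cell_id = c("a", "b"), region = c("CBL", "CTX"))
  g4 <- build_sp_graph(mk_events(4), cells)
  expect_identical(g4$edges$co_count, 4L)
  expect_false(g4$edges$sp_flag)
  g5 <- build_sp_graph(mk_events(5), cells)
  expect_true(g5$edges$sp_flag)
})

test_that("multiple onsets of one cell in one event count once", {
  se <- tibble::tibble(
    event_id = 1L, t0 = 10, t1 = 10.2, n_participants = 2L,
    participants = list(c("a", "b"))
  )
  ev_graph <- build_sp_graph(se, tibble::tibble(cell_id = c("a", "b"),
                                                region = "CBL"))
  expect_identical(ev_graph$edges$co_count, 1L)
})

test_that("full SP pipeline equals the brute-force implementation", {
  set.seed(23)
  ev <- tibble::tibble(
    cell_id = sample(paste0("c", 1:8), 50, replace = TRUE),
    onset_s = round(runif(50, 0, 40), 3)
  )
  cells <- tibble::tibble(cell_id = paste0("c", 1:8),
                          region = rep(c("CBL", "CTX"), each = 4))
  elapsed <- system.time({
    sp <- detect_sp(ev, cells, duration_s = 40, h_s = 0.1, dt_s = 0.02)
  })[["elapsed"]]
  expect_lt(elapsed, 1)

  S_oracle <- brute_kernel_sum(ev$onset_s, sp$kernel_sum$t, 0.1)
  expect_equal(sp$kernel_sum$S, S_oracle, tolerance = 1e-9)

  thr <- mean(S_oracle) + 2 * sd(S_oracle)
  ivs <- brute_sync_intervals(sp$kernel_sum$t, S_oracle, thr, 0.02)
  # intervals with no onsets inside carry no co-firing and are dropped
  has_onset <- vapply(ivs, function(iv) {
    any(ev$onset_s >= iv[1] & ev$onset_s < iv[2])
  }, logical(1))
  expect_identical(nrow(sp$sync_events), sum(has_onset))

  counts <- brute_pair_counts(ivs, ev)
  expect_identical(nrow(sp$graph$edges), length(counts))
  for (k in seq_len(nrow(sp$graph$edges))) {
    key <- paste(sp$graph$edges$cell_a[k], sp$graph$edges$cell_b[k], sep = "|")
    expect_identical(sp$graph$edges$co_count[k], as.integer(counts[[key]]))
  }
})

test_that("co-firing counts are invariant to a common time shift", {
  set.seed(3)
  ev <- tibble::tibble(
    cell_id = sample(paste0("c", 1:6), 40, replace = TRUE),
    onset_s = runif(40, 5, 35)
  )
  cells <- tibble::tibble(cell_id = paste0("c", 1:6), region = "CBL")
  g1 <- detect_sp(ev, cells, duration_s = 50)$graph
  ev2 <- dplyr::mutate(ev, onset_s = onset_s + 7)
  g2 <- detect_sp(ev2, cells, duration_s = 57)$graph
  expect_equal(g1$edges[c("cell_a", "cell_b", "co_count")],
               g2$edges[c("cell_a", "cell_b", "co_count")])
})

test_that("raising min_co never adds SP edges", {
  set.seed(5)
  ev <- tibble::tibble(
    cell_id = sample(paste0("c", 1:8), 120, replace = TRUE),
    onset_s = runif(120, 0, 30)
  )
  cells <- tibble::tibble(cell_id = paste0("c", 1:8), region = "CBL")
  ks <- kernel_sum(ev, duration_s = 30)
  se <- detect_sync_events(ks, ev)
  n_sp <- vapply(1:8, function(mc) {
    sum(build_sp_graph(se, cells, min_co = mc)$edges$sp_flag)
  }, integer(1))
  expect_true(all(diff(n_sp) <= 0))
})

test_that("scope labels split within/across and participation is set-valued", {
  se <- tibble::tibble(
    event_id = 1:6, t0 = 1:6 * 10, t1 = 1:6 * 10 + 0.2,
    n_participants = 3L,
    participants = replicate(6, c("cbl1", "cbl2", "ctx1"), simplify = FALSE)
  )
  cells <- tibble::tibble(cell_id = c("cbl1", "cbl2", "ctx1", "ctx2"),
                          region = c("CBL", "CBL", "CTX", "CTX"))
  g <- build_sp_graph(se, cells)
  sc <- classify_sp_scope(g)
  expect_setequal(unique(sc$sp_edges$scope), c("within_CBL", "across"))
  # cbl1/cbl2 have both within and across participation
  p <- sc$participation
  expect_equal(p$frac_within[p$region == "CBL"], 1)
  expect_equal(p$frac_across[p$region == "CBL"], 1)
  expect_equal(p$frac_within[p$region == "CTX"], 0)
  expect_equal(p$frac_across[p$region == "CTX"], 0.5)
  expect_true(all(p$frac_within >= 0 & p$frac_within <= 1))

  # single-region graph has no across edges
  mono <- build_sp_graph(se, dplyr::mutate(cells, region = "CBL"))
  expect_false(any(tidy(mono)$scope == "across"))
})

test_that("planted ensembles are recovered as SPs with few false pairs", {
  # chance co-firing at Poisson baseline rates grows linearly with session
  # length while a planted ensemble fires a fixed number of times, so the
  # recovery benchmark uses compact sessions: a 6-cell cross-region
  # ensemble firing 10 times in one minute among 24 cells
  res <- vapply(1:5, function(seed) {
    s <- simulate_session(ensemble_config(seed = seed, duration_s = 60,
                                          n_cbl = 12L, n_ctx = 12L,
                                          frac = 0.25, sp_count = 10L))
    truth <- s$truth
    sp <- detect_sp(truth$onsets, s$traces$cells,
                    duration_s = truth$config$duration_s)
    members <- truth$ensemble$cell_id[truth$ensemble$is_member]
    planted <- utils::combn(sort(members), 2)
    flagged <- sp$graph$edges[sp$graph$edges$sp_flag, ]
    hit <- vapply(seq_len(ncol(planted)), function(j) {
      any(flagged$cell_a == planted[1, j] & flagged$cell_b == planted[2, j])
    }, logical(1))
    c(n_hit = sum(hit), n_flag = nrow(flagged))
  }, numeric(2))
  expect_identical(sum(res["n_hit", ]), 5 * 15)
  pooled_fdr <- (sum(res["n_flag", ]) - sum(res["n_hit", ])) /
    sum(res["n_flag", ])
  expect_lte(pooled_fdr, 0.05)
})
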