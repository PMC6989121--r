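# Synchronous-pattern (SP) detection. Event onsets from all cells are
# convolved with a unit-peak Epanechnikov kernel and summed into a population
# kernel sum S(t); maximal stretches with S above mean + 2*sigma are global
# synchronous events; cells whose onsets fall inside the same event co-fire
# once, and pairs that co-fire at least `min_co` (default 5) times are
# synchronous pairs, labeled within- or across-region by their endpoints.

#' Epanechnikov kernel (unit peak)
#'
#' `k(t) = 1 - (t / h)^2` for `|t| <= h`, 0 outside. The half-width `h`
#' (seconds) is the only time-like parameter; the default 0.1 s spans about
#' +/- 3 frames at 30 Hz.
#'
#' @param t numeric times (seconds).
#' @param h_s kernel half-width, > 0.
#' @return kernel values in `[0, 1]`.
#' @export
epanechnikov <- function(t, h_s = 0.1) {
  stopifnot(h_s > 0)
  ifelse(abs(t) <= h_s, 1 - (t / h_s)^2, 0)
}

#' Population kernel sum over event onsets
#'
#' Evaluates `S(t) = sum_cells sum_onsets k(t - onset)` on a uniform grid and
#' attaches its mean, SD and the `mean + 2*sigma` synchrony threshold. The
#' moments are computed over the entire grid, supra-threshold stretches
#' included; set `robust = TRUE` to use median/MAD instead.
#'
#' @param events event table (`cell_id`, `onset_s`; `region` carried along).
#' @param h_s Epanechnikov half-width (seconds).
#' @param dt_s grid step; must satisfy `dt_s <= h_s / 4` so the kernel is
#'   well resolved (default 0.01).
#' @param duration_s session duration (grid spans `[0, duration_s]`).
#' @param n_sigma threshold multiplier (default 2).
#' @param robust use median + MAD-based moments.
#' @return A `kernel_sum` object: list with `t`, `S`, `mu`, `sigma`,
#'   `threshold`, `h_s`, `dt_s`.
#' @export
kernel_sum <- function(events, h_s = 0.1, dt_s = 0.01, duration_s = NULL,
                       n_sigma = 2, robust = FALSE) {
  if (nrow(events) == 0L) abort("kernel_sum needs at least one event")
  stopifnot(h_s > 0, dt_s > 0)
  if (dt_s > h_s / 4) abort("dt_s must be <= h_s / 4 to resolve the kernel")
  if (is.null(duration_s)) duration_s <- max(events$onset_s) + h_s
  grid <- seq(0, duration_s, by = dt_s)
  S <- numeric(length(grid))
  half_n <- ceiling(h_s / dt_s)
  for (on in events$onset_s) {
    ic <- round(on / dt_s) + 1
    idx <- max(1L, ic - half_n - 1L):min(length(grid), ic + half_n + 1L)
    S[idx] <- S[idx] + epanechnikov(grid[idx] - on, h_s)
  }
  if (robust) {
    mu <- median(S)
    sigma <- mad(S)
  } else {
    mu <- mean(S)
    sigma <- sd(S)
  }
  structure(
    list(t = grid, S = S, mu = mu, sigma = sigma,
         threshold = mu + n_sigma * sigma, h_s = h_s, dt_s = dt_s),
    class = "kernel_sum"
  )
}

#' @export
print.kernel_sum <- function(x, ...) {
  cat(sprintf(
    "<kernel_sum> %d grid points, dt = %g s, h = %g s\n  mu = %.4g, sigma = %.4g, threshold = %.4g\n",
    length(x$t), x$dt_s, x$h_s, x$mu, x$sigma, x$threshold
  ))
  invisible(x)
}

#' @export
tidy.kernel_sum <- function(x, ...) tibble(t = x$t, S = x$S)

#' @export
glance.kernel_sum <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, threshold = x$threshold,
         h_s = x$h_s, dt_s = x$dt_s, n_grid = length(x$t))
}

#' Global synchronous events from a kernel sum
#'
#' Maximal runs of grid points with `S > threshold` become half-open
#' intervals `[first_t, last_t + dt)`; participants are the cells with at
#' least one onset inside the interval (an onset exactly at `t1` is not a
#' participant). Runs separated by one or more sub-threshold grid points are
#' distinct events.
#'
#' @param ks a [kernel_sum()].
#' @param events the event table the kernel sum was built from.
#' @return A tibble with columns `event_id`, `t0`, `t1`, `n_participants`,
#'   `participants` (list column of cell ids).
#' @export
detect_sync_events <- function(ks, events) {
  stopifnot(inherits(ks, "kernel_sum"))
  above <- ks$S > ks$threshold
  empty <- tibble(event_id = integer(0), t0 = numeric(0), t1 = numeric(0),
                  n_participants = integer(0), participants = list())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  t0 <- ks$t[starts[keep]]
  t1 <- ks$t[ends[keep]] + ks$dt_s
  rows <- purrr::map2(t0, t1, function(a, b) {
    inside <- events$onset_s >= a & events$onset_s < b
    unique(events$cell_id[inside])
  })
  out <- tibble(
    event_id = seq_along(t0), t0 = t0, t1 = t1,
    n_participants = lengths(rows), participants = rows
  )
  # a run can in principle contain no onset (overlapping kernel tails);
  # such intervals carry no co-firing information and are dropped
  out[out$n_participants > 0L, ]
}

#' Build the synchronous-pair (SP) graph
#'
#' For every unordered pair of cells, `co_count` is the number of synchronous
#' events containing at least one onset of each cell -- multiple onsets of
#' one cell inside one event count once. Pairs with `co_count >= min_co`
#' (default 5, boundary inclusive) are flagged as SPs.
#'
#' @param sync_events output of [detect_sync_events()].
#' @param cells roster tibble (`cell_id`, `region`), e.g. `tm$cells`.
#' @param min_co minimum shared events for the SP flag.
#' @return An `sp_graph` object: list with `nodes` (cell roster), `edges`
#'   (`cell_a`, `cell_b`, `co_count`, `sp_flag`), `min_co`, `n_sync_events`.
#' @export
build_sp_graph <- function(sync_events, cells, min_co = 5L) {
  stopifnot(min_co >= 1L)
  cells <- as_tibble(cells)[c("cell_id", "region")]
  counts <- new.env(parent = emptyenv())
  for (p in sync_events$participants) {
    p <- sort(unique(p))
    if (length(p) < 2L) next
    pairs <- utils::combn(p, 2L)
    for (j in seq_len(ncol(pairs))) {
      key <- paste(pairs[1L, j], pairs[2L, j], sep = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  edges <- if (length(keys) == 0L) {
    tibble(cell_a = character(0), cell_b = character(0),
           co_count = integer(0), sp_flag = logical(0))
  } else {
    ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    tibble(
      cell_a = ab[, 1L], cell_b = ab[, 2L],
      co_count = vapply(keys, function(k) as.integer(counts[[k]]), integer(1),
                        USE.NAMES = FALSE)
    ) |>
      dplyr::mutate(sp_flag = .data$co_count >= min_co) |>
      dplyr::arrange(.data$cell_a, .data$cell_b)
  }
  structure(
    list(nodes = cells, edges = edges, min_co = as.integer(min_co),
         n_sync_events = nrow(sync_events)),
    class = "sp_graph"
  )
}

#' @export
print.sp_graph <- function(x, ...) {
  cat(sprintf(
    "<sp_graph> %d cells, %d co-firing pairs, %d SPs (min_co = %d, %d sync events)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$sp_flag), x$min_co,
    x$n_sync_events
  ))
  invisible(x)
}

#' @export
tidy.sp_graph <- function(x, ...) {
  reg <- setNames(x$nodes$region, x$nodes$cell_id)
  dplyr::mutate(
    x$edges,
    region_a = unname(reg[.data$cell_a]),
    region_b = unname(reg[.data$cell_b]),
    scope = ifelse(.data$region_a == .data$region_b,
                   paste0("within_", .data$region_a), "across")
  )
}

#' @export
glance.sp_graph <- function(x, ...) {
  e <- tidy(x)
  sp <- e[e$sp_flag, ]
  tibble(
    n_cells = nrow(x$nodes),
    n_pairs = nrow(e),
    n_sp = nrow(sp),
    n_sp_across = sum(sp$scope == "across"),
    n_sync_events = x$n_sync_events,
    min_co = x$min_co
  )
}

#' Classify SP scope and per-region participation
#'
#' Labels every edge `within_<region>` or `across` from its endpoints'
#' regions, and summarises per region the fraction of cells that carry at
#' least one within-SP edge and at least one across-SP edge (a cell may have
#' both; the sets overlap).
#'
#' @param graph an [build_sp_graph()] result.
#' @return A list with `edges` (labeled edge tibble, SPs only in
#'   `sp_edges`) and `participation` (per-region tibble: `n_cells`,
#'   `frac_within`, `frac_across`).
#' @export
classify_sp_scope <- function(graph) {
  stopifnot(inherits(graph, "sp_graph"))
  e <- tidy(graph)
  sp <- e[e$sp_flag, ]
  participation <- dplyr::bind_rows(lapply(
    split(graph$nodes, graph$nodes$region),
    function(nd) {
      r <- nd$region[1]
      within_cells <- unique(c(
        sp$cell_a[sp$scope == paste0("within_", r)],
        sp$cell_b[sp$scope == paste0("within_", r)]
      ))
      across_cells <- unique(c(
        sp$cell_a[sp$scope == "across"], sp$cell_b[sp$scope == "across"]
      ))
      tibble(
        region = r,
        n_cells = nrow(nd),
        frac_within = mean(nd$cell_id %in% within_cells),
        frac_across = mean(nd$cell_id %in% across_cells)
      )
    }
  ))
  list(edges = e, sp_edges = sp, participation = participation)
}

#' Run the whole SP pipeline on an event table
#'
#' Convenience wrapper: [kernel_sum()] over all cells, sync-event scan,
#' pair counting, scope classification.
#'
#' @inheritParams kernel_sum
#' @param cells cell roster (`cell_id`, `region`).
#' @param min_co SP co-firing threshold.
#' @return A list: `kernel_sum`, `sync_events`, `graph`, `scope`.
#' @export
detect_sp <- function(events, cells, duration_s, h_s = 0.1, dt_s = 0.01,
                      min_co = 5L, n_sigma = 2, robust = FALSE) {
  ks <- kernel_sum(events, h_s = h_s, dt_s = dt_s, duration_s = duration_s,
                   n_sigma = n_sigma, robust = robust)
  se <- detect_sync_events(ks, events)
  g <- build_sp_graph(se, cells, min_co = min_co)
  list(kernel_sum = ks, sync_events = se, graph = g,
       scope = classify_sp_scope(g))
}
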