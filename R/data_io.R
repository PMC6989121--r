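# Session artifact I/O: trace tables, IMU logs, stimulation logs, event
# tables, and timestamp alignment across streams sampled at different rates.
#
# All artifacts are comma-separated text with a mandatory header row and "."
# decimal; times are seconds from session start; intervals are half-open
# [t0, t1).

#' Construct a trace matrix
#'
#' A `trace_matrix` holds cells x frames fluorescence (or deconvolved
#' activity) together with per-frame timestamps, per-cell region labels and
#' the nominal frame rate. It is the in-memory form of an extracted-source
#' table (e.g. CNMF-E `C_raw` exported to CSV).
#'
#' @param values numeric matrix, cells in rows, frames in columns.
#' @param t per-frame timestamps in seconds, strictly increasing.
#' @param cell_ids character vector of cell identifiers (row names).
#' @param region per-cell region label (e.g. `"CBL"`, `"CTX"`), recycled if
#'   length 1.
#' @param frame_rate_hz nominal acquisition rate; inferred from `t` when `NULL`.
#'
#' @return A `trace_matrix` object. Cells whose trace is constant over the
#'   whole session are retained but flagged in `$cells$flag_constant`.
#' @export
trace_matrix <- function(values, t, cell_ids = rownames(values),
                         region = "CBL", frame_rate_hz = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  cell_ids <- as.character(cell_ids)
  if (length(region) == 1L) region <- rep(region, nrow(values))
  stopifnot(length(cell_ids) == nrow(values), length(region) == nrow(values),
            length(t) == ncol(values))
  assert_strictly_increasing(t)
  if (anyNA(values)) abort("trace matrix contains missing values")
  if (is.null(frame_rate_hz)) {
    frame_rate_hz <- if (length(t) > 1L) 1 / median(diff(t)) else NA_real_
  }
  rownames(values) <- cell_ids
  structure(
    list(
      values = values,
      t = as.numeric(t),
      cells = tibble(
        cell_id = cell_ids,
        region = as.character(region),
        flag_constant = apply(values, 1L, function(r) diff(range(r)) == 0)
      ),
      frame_rate_hz = frame_rate_hz
    ),
    class = "trace_matrix"
  )
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf(
    "<trace_matrix> %d cells x %d frames, %.6g-%.6g s, %.3g Hz\n",
    nrow(x$values), ncol(x$values), min(x$t), max(x$t), x$frame_rate_hz
  ))
  print(dplyr::count(x$cells, .data$region))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Tidy a trace matrix into long form
#'
#' @param x a `trace_matrix`.
#' @param ... unused.
#' @return A tibble with columns `cell_id`, `region`, `t`, `value`.
#' @export
tidy.trace_matrix <- function(x, ...) {
  tibble(
    cell_id = rep(x$cells$cell_id, each = length(x$t)),
    region = rep(x$cells$region, each = length(x$t)),
    t = rep(x$t, times = nrow(x$values)),
    value = as.numeric(t(x$values))
  )
}

#' Read a trace table from delimited text
#'
#' The canonical schema is one `t` column (seconds) plus one column per cell;
#' `region_map` assigns every cell column a region label.
#'
#' @param path CSV file path.
#' @param region_map named character vector or two-column data frame
#'   (`cell_id`, `region`) mapping every cell column to a region.
#' @return A [trace_matrix()].
#' @export
read_trace_table <- function(path, region_map) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"t" %in% names(df)) abort("trace table must have a 't' column")
  cell_cols <- setdiff(names(df), "t")
  if (length(cell_cols) == 0L) abort("trace table has no cell columns")
  if (anyNA(df)) abort("trace table contains missing values")
  assert_strictly_increasing(df$t)
  if (is.data.frame(region_map)) {
    region_map <- setNames(region_map$region, region_map$cell_id)
  }
  unmapped <- setdiff(cell_cols, names(region_map))
  if (length(unmapped) > 0L) {
    abort(sprintf("unmapped cell id(s): %s", paste(unmapped, collapse = ", ")))
  }
  trace_matrix(
    values = t(as.matrix(df[cell_cols])),
    t = df$t,
    cell_ids = cell_cols,
    region = unname(region_map[cell_cols])
  )
}

#' Write a trace table
#'
#' Inverse of [read_trace_table()]; round-trips values to full precision.
#'
#' @param tm a `trace_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(tm, path) {
  df <- as_tibble(t(tm$values))
  df <- dplyr::bind_cols(tibble(t = tm$t), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Convert raw IMU counts to g
#'
#' The accelerometer reports signed counts over a +/- 2 g range where one
#' bit corresponds to 0.061 mg, so `g = counts * 0.061e-3`. The map is pure,
#' linear and odd; saturation handling is left to the caller.
#'
#' @param counts integer (or numeric) vector of raw sensor counts.
#' @return numeric vector of accelerations in g.
#' @export
imu_counts_to_g <- function(counts) {
  as.numeric(counts) * 0.061e-3
}

#' Construct an accelerometer record
#'
#' @param t seconds, strictly increasing.
#' @param x,y,z acceleration in g (nominal sensor range +/- 2 g).
#' @param nominal_rate_hz nominal IMU sample rate (default 104).
#' @return A tibble of class `accel_record` with columns `t`, `x`, `y`, `z`.
#' @export
accel_record <- function(t, x, y, z, nominal_rate_hz = 104) {
  stopifnot(length(t) == length(x), length(t) == length(y),
            length(t) == length(z))
  assert_strictly_increasing(t)
  if (any(abs(c(x, y, z)) > 2.05)) {
    warn("acceleration exceeds +/- 2.05 g; check counts-to-g conversion")
  }
  out <- tibble(t = as.numeric(t), x = as.numeric(x),
                y = as.numeric(y), z = as.numeric(z))
  attr(out, "nominal_rate_hz") <- nominal_rate_hz
  class(out) <- c("accel_record", class(out))
  out
}

#' Read / write accelerometer CSV logs
#'
#' Schema: columns `t`, `x`, `y`, `z` (seconds and g). Use
#' [imu_counts_to_g()] first if the log stores raw counts.
#'
#' @param path CSV path.
#' @param nominal_rate_hz nominal IMU rate attached to the record.
#' @return [read_accel_table()] returns an [accel_record()];
#'   [write_accel_table()] returns `path` invisibly.
#' @export
read_accel_table <- function(path, nominal_rate_hz = 104) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort("accel table must have columns t, x, y, z")
  }
  accel_record(df$t, df$x, df$y, df$z, nominal_rate_hz = nominal_rate_hz)
}

#' @rdname read_accel_table
#' @param acc an `accel_record`.
#' @export
write_accel_table <- function(acc, path) {
  readr::write_csv(as_tibble(acc)[c("t", "x", "y", "z")], path,
                   progress = FALSE)
  invisible(path)
}

#' Construct a stimulation log
#'
#' @param onsets stimulus onset times in seconds, sorted.
#' @param duration_s stimulus duration(s) in seconds, recycled.
#' @param site site label(s), recycled.
#' @param current_ma optional drive current metadata.
#' @return A tibble of class `stim_log` with columns `onset_s`, `duration_s`,
#'   `site`, `current_ma`.
#' @export
stim_log <- function(onsets, duration_s, site = "site1", current_ma = NA_real_) {
  if (is.unsorted(onsets)) abort("stimulus onsets must be sorted")
  if (any(duration_s <= 0)) abort("stimulus duration must be positive")
  out <- tibble(
    onset_s = as.numeric(onsets),
    duration_s = as.numeric(rep_len(duration_s, length(onsets))),
    site = rep_len(as.character(site), length(onsets)),
    current_ma = rep_len(as.numeric(current_ma), length(onsets))
  )
  class(out) <- c("stim_log", class(out))
  out
}

#' Read / write stimulation CSV logs
#'
#' Schema: columns `onset_s`, `duration_s`, `site`, optionally `current_ma`.
#'
#' @param path CSV path.
#' @return [read_stim_table()] returns a [stim_log()];
#'   [write_stim_table()] returns `path` invisibly.
#' @export
read_stim_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("onset_s", "duration_s") %in% names(df))) {
    abort("stim table must have columns onset_s, duration_s")
  }
  stim_log(df$onset_s, df$duration_s,
           site = df$site %||% "site1",
           current_ma = df$current_ma %||% NA_real_)
}

#' @rdname read_stim_table
#' @param stim a `stim_log`.
#' @export
write_stim_table <- function(stim, path) {
  readr::write_csv(as_tibble(stim), path, progress = FALSE)
  invisible(path)
}

#' Align two timestamp streams by nearest neighbor
#'
#' Maps every imaging frame to the accelerometer sample minimizing the
#' absolute time offset; pairs farther apart than `tolerance_s` are dropped
#' and counted. The default tolerance, 15 ms, is about half a 30 Hz frame and
#' matches a per-frame IMU FIFO read-out.
#'
#' @param frame_ts frame timestamps, strictly increasing, seconds.
#' @param accel_ts accelerometer timestamps, strictly increasing, seconds.
#' @param tolerance_s maximum |offset| retained.
#' @return A tibble with columns `frame_idx`, `accel_idx`, `offset_s`
#'   (frame time minus accel time) and attribute `n_dropped`.
#' @export
align_streams <- function(frame_ts, accel_ts, tolerance_s = 0.015) {
  if (length(frame_ts) == 0L || length(accel_ts) == 0L) {
    abort("cannot align empty timestamp series")
  }
  stopifnot(tolerance_s > 0)
  assert_strictly_increasing(frame_ts, "frame timestamps")
  assert_strictly_increasing(accel_ts, "accel timestamps")
  idx <- nearest_index(frame_ts, accel_ts)
  offset <- frame_ts - accel_ts[idx]
  keep <- abs(offset) <= tolerance_s
  out <- tibble(
    frame_idx = seq_along(frame_ts)[keep],
    accel_idx = idx[keep],
    offset_s = offset[keep]
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}
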