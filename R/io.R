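# Plain-text interchange: CSV for trajectories/markers/strides/tables,
# JSON for configuration and summary metadata.

marker_cols <- c("time_s", "RASI_z_mm", "LASI_z_mm", "RPSI_z_mm", "LPSI_z_mm")

#' Read / write pelvic marker CSV files
#'
#' Columns `time_s, RASI_z_mm, LASI_z_mm, RPSI_z_mm, LPSI_z_mm` (vertical
#' coordinates in millimetres on a uniform time grid, 120 Hz by convention).
#'
#' @param path File path.
#' @return `read_markers_csv()` returns a `marker_set` tibble.
#' @export
read_markers_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing_col <- setdiff(marker_cols, names(df))
  if (length(missing_col) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing_col, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[marker_cols]))
  if (length(bad) > 0) {
    abort(sprintf("%s: incomplete row at line %d", path, bad[1] + 1L))
  }
  dt <- diff(df$time_s)
  if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
    abort(sprintf("%s: `time_s` is not uniformly sampled", path))
  }
  out <- as_tibble(df[marker_cols])
  structure(out, class = c("marker_set", class(out)), rate = 1 / dt[1])
}

#' @rdname read_markers_csv
#' @param markers A `marker_set` tibble.
#' @export
write_markers_csv <- function(markers, path) {
  readr::write_csv(as_tibble(markers)[marker_cols], path)
  invisible(path)
}

#' Read / write stride-interval CSV files
#'
#' Columns `cycle_index, stride_s` (one stride duration in seconds per gait
#' cycle, in temporal order).
#'
#' @param path File path.
#' @return `read_strides_csv()` returns a `stride_series` tibble.
#' @export
read_strides_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("cycle_index", "stride_s") %in% names(df))) {
    abort(sprintf("%s: expected columns `cycle_index`, `stride_s`", path))
  }
  if (any(!is.finite(df$stride_s)) || any(df$stride_s <= 0)) {
    abort(sprintf("%s: strides must be positive and finite", path))
  }
  out <- as_tibble(df[c("cycle_index", "stride_s")])
  structure(out, class = c("stride_series", class(out)))
}

#' @rdname read_strides_csv
#' @param strides A `stride_series` tibble.
#' @export
write_strides_csv <- function(strides, path) {
  readr::write_csv(as_tibble(strides)[c("cycle_index", "stride_s")], path)
  invisible(path)
}

#' Read / write COM trajectory CSV files
#'
#' Columns `time_s, Q_m, P_mps`.
#'
#' @param path File path.
#' @return `read_trajectory_csv()` returns a [com_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "Q_m", "P_mps") %in% names(df))) {
    abort(sprintf("%s: expected columns `time_s`, `Q_m`, `P_mps`", path))
  }
  as_com_trajectory(tibble(time_s = df$time_s, q_m = df$Q_m, p_mps = df$P_mps))
}

#' @rdname read_trajectory_csv
#' @param traj A [com_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(
    tibble(time_s = traj$time_s, Q_m = traj$q_m, P_mps = traj$p_mps), path)
  invisible(path)
}
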