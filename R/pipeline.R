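# End-to-end study runners: simulate -> files, markers -> invariant outputs,
# metric tables -> comparison report. These are the programmatic equivalents
# of the command-line subcommands in `inst/cli/adiagait.R`.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic recording session
#'
#' Generates one synthetic "participant": a stochastic-oscillator COM
#' trajectory rendered as four pelvic marker tracks at the camera rate, and
#' a fractal stride-interval series. Writes `markers.csv`, `strides.csv` and
#' a `truth.json` with every generator parameter (for recovery tests), the
#' configuration hash and the package version.
#'
#' @param out_dir Output directory (created if needed).
#' @param osc An [osc_config()].
#' @param strides A [stride_config()].
#' @param rate_out Camera rate for the marker files (Hz).
#' @param marker_noise_sd Marker measurement noise SD (mm).
#' @param seed Master seed; fills any unset component seeds
#'   deterministically.
#' @return Invisibly, a named list of the written file paths.
#' @examples
#' \donttest{
#' paths <- run_simulation(tempfile(), osc = osc_config(duration = 30),
#'                         seed = 1)
#' }
#' @export
run_simulation <- function(out_dir,
                           osc = osc_config(),
                           strides = stride_config(),
                           rate_out = 120,
                           marker_noise_sd = 0.5,
                           seed = NULL) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.null(osc$seed)) osc$seed <- seed
    if (is.null(strides$seed)) strides$seed <- seed + 1L
  }
  marker_seed <- if (is.null(seed)) NULL else seed + 2L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  traj <- simulate_oscillator(osc)
  markers <- synthesize_markers(traj, rate_out = rate_out,
                                marker_noise_sd = marker_noise_sd,
                                seed = marker_seed)
  stride_tbl <- generate_fgn_strides(strides)

  paths <- list(
    markers = file.path(out_dir, "markers.csv"),
    strides = file.path(out_dir, "strides.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_markers_csv(markers, paths$markers)
  write_strides_csv(stride_tbl, paths$strides)

  truth <- list(
    oscillator = osc[c("omega0", "epsilon", "tau", "amplitude0", "duration",
                       "dt", "seed", "noise", "integrator")],
    strides = strides[c("n_strides", "hurst_target", "mean_si", "cv_target",
                        "seed")],
    markers = list(rate_out = rate_out, marker_noise_sd = marker_noise_sd,
                   seed = marker_seed),
    package_version = pkg_version()
  )
  truth$config_hash <- config_hash(truth)
  write_json_file(truth, paths$truth)
  invisible(paths)
}

#' Process a marker recording into invariant outputs
#'
#' Runs the full kinematic and cycle analysis on a marker file (or
#' `marker_set` tibble): COM extraction, adaptive filtering, upsampling,
#' differentiation, cycle segmentation, per-cycle energetics and the
#' 1200-bin mean attractor. Writes `qp.csv` (trajectory), `cycles.csv`
#' (per-cycle table), `attractor.csv` and `invariant.json` (aggregates,
#' filter cutoff, configuration hash, package version).
#'
#' @param markers Path to a marker CSV or a `marker_set` tibble.
#' @param out_dir Output directory (created if needed).
#' @param power_fraction Adaptive-filter power fraction.
#' @param factor Upsampling factor.
#' @param bins Attractor bins.
#' @param ... Passed to [detect_steps()].
#' @return Invisibly, a list with the written paths plus the in-memory
#'   `trajectory`, `cycles` (gait-cycle table) and `attractor`.
#' @export
run_processing <- function(markers, out_dir, power_fraction = 0.9999,
                           factor = 10, bins = 1200, ...) {
  if (is.character(markers)) markers <- read_markers_csv(markers)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  traj <- process_markers(markers, power_fraction = power_fraction,
                          factor = factor)
  cyc <- invariant_table(traj, ...)
  att <- mean_attractor(traj, cycles = cyc[c("cycle", "start_idx", "end_idx")],
                        bins = bins)

  paths <- list(
    trajectory = file.path(out_dir, "qp.csv"),
    cycles = file.path(out_dir, "cycles.csv"),
    attractor = file.path(out_dir, "attractor.csv"),
    invariant = file.path(out_dir, "invariant.json")
  )
  write_trajectory_csv(traj, paths$trajectory)
  readr::write_csv(
    tibble(cycle = cyc$cycle, T_s = cyc$t_s, f_hz = cyc$f_hz,
           Ekbar_Jkg = cyc$ekbar_jkg, f_rel = cyc$f_rel, ek_rel = cyc$ek_rel),
    paths$cycles)
  readr::write_csv(as_tibble(att), paths$attractor)

  meta <- list(
    settings = list(power_fraction = power_fraction, factor = factor,
                    bins = bins, cutoff_hz = attr(traj, "cutoff_hz")),
    aggregates = as.list(glance(cyc)),
    package_version = pkg_version()
  )
  meta$config_hash <- config_hash(meta)
  write_json_file(meta, paths$invariant)
  invisible(c(paths, list(trajectory_data = traj, cycles_data = cyc,
                          attractor_data = att)))
}

metric_names <- c(si_s = "SI (s)", cv = "CV", hurst = "H",
                  minkowski_d = "D", sampen = "S")

#' Compare two per-subject metric tables
#'
#' Takes two tables of stride-interval metrics (one row per subject, columns
#' `subject`, `si_s`, `cv`, `hurst`, `minkowski_d`, `sampen`, e.g. from
#' [si_metrics()] per subject), pairs them by subject ID, and runs the
#' normality-gated paired comparison per metric. The report follows the
#' usual convention: mean +/- SD when the t-test branch was taken, median
#' [q1-q3] for the Wilcoxon branch.
#'
#' @param a,b Metric tables (tibbles or CSV paths) for the two conditions.
#' @param labels Length-2 condition labels used in the report.
#' @param alpha Significance level for the normality gate.
#' @return A list with `comparisons` (one row per metric: test chosen,
#'   statistic, p-value), `report` (condition-by-metric display table), and
#'   `markdown` (the report as a Markdown table).
#' @export
run_comparison <- function(a, b, labels = c("A", "B"), alpha = 0.05) {
  if (is.character(a)) a <- readr::read_csv(a, show_col_types = FALSE)
  if (is.character(b)) b <- readr::read_csv(b, show_col_types = FALSE)
  need <- c("subject", names(metric_names))
  for (tb in list(a, b)) {
    missing_col <- setdiff(need, names(tb))
    if (length(missing_col) > 0) {
      abort(sprintf("metric table missing column(s): %s",
                    paste(missing_col, collapse = ", ")))
    }
  }
  only_a <- setdiff(a$subject, b$subject)
  only_b <- setdiff(b$subject, a$subject)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(sprintf("unmatched subject IDs: %s",
                  paste(c(only_a, only_b), collapse = ", ")))
  }
  b <- b[match(a$subject, b$subject), ]

  comparisons <- purrr::map_dfr(names(metric_names), function(mn) {
    cmp <- tryCatch(
      paired_compare(a[[mn]], b[[mn]], alpha = alpha),
      error = function(e) tibble(test = "degenerate", statistic = NA_real_,
                                 p_value = NA_real_, shapiro_p = NA_real_,
                                 n = nrow(a)))
    dplyr::mutate(cmp, metric = metric_names[[mn]], .before = 1)
  })

  fmt_cell <- function(v, test) {
    if (test == "degenerate") {
      sprintf("%.4g (degenerate)", mean(v))
    } else if (test == "paired-t") {
      sprintf("%.4g ± %.3g", mean(v), sd(v))
    } else {
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.4g [%.4g–%.4g]", q[2], q[1], q[3])
    }
  }
  report <- tibble(condition = c(labels, "p"))
  for (mn in names(metric_names)) {
    test <- comparisons$test[comparisons$metric == metric_names[[mn]]]
    pv <- comparisons$p_value[comparisons$metric == metric_names[[mn]]]
    report[[metric_names[[mn]]]] <- c(fmt_cell(a[[mn]], test),
                                      fmt_cell(b[[mn]], test),
                                      format(round(pv, 3)))
  }

  header <- paste(c("Condition", metric_names), collapse = " | ")
  sep <- paste(rep("---", length(metric_names) + 1), collapse = " | ")
  rows <- apply(report, 1, paste, collapse = " | ")
  markdown <- paste(c(header, sep, rows), collapse = "\n")

  list(comparisons = comparisons, report = report, markdown = markdown)
}
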