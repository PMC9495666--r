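#' Whole-body COM vertical position from pelvic markers
#'
#' The vertical center-of-mass trajectory is estimated as the per-sample
#' arithmetic mean of the four pelvic markers (RASI, LASI, RPSI, LPSI),
#' converted from millimetres to metres. Constant marker offsets (anterior
#' vs. posterior iliac spines) cancel in the mean as long as they sum to
#' zero.
#'
#' @param markers A `marker_set` tibble (see [synthesize_markers()]) or any
#'   data frame with columns `time_s`, `RASI_z_mm`, `LASI_z_mm`, `RPSI_z_mm`,
#'   `LPSI_z_mm` on a uniform time grid.
#' @return A `gait_signal` with the COM vertical position in metres.
#' @examples
#' traj <- simulate_oscillator(osc_config(duration = 20, seed = 1))
#' mk <- synthesize_markers(traj, marker_noise_sd = 0, seed = 1)
#' q <- com_from_markers(mk)
#' @export
com_from_markers <- function(markers) {
  labels <- c("RASI_z_mm", "LASI_z_mm", "RPSI_z_mm", "LPSI_z_mm")
  missing_lab <- setdiff(labels, names(markers))
  if (length(missing_lab) > 0) {
    abort(sprintf("marker set is missing column(s): %s",
                  paste(missing_lab, collapse = ", ")))
  }
  mat <- as.matrix(markers[labels])
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    abort(sprintf("marker trajectories contain gaps (first NaN at sample %d); fill gaps upstream", bad))
  }
  q_m <- rowMeans(mat) / 1000
  rate <- attr(markers, "rate")
  if (is.null(rate)) {
    return(as_gait_signal(tibble(time_s = markers$time_s, value = q_m), unit = "m"))
  }
  gait_signal(q_m, rate = rate, t0 = markers$time_s[1], unit = "m")
}

# Cutoff selection for the adaptive filter. The filter must keep
# `power_fraction` of the mean-removed signal's power after the
# forward-backward 4th-order Butterworth pass, whose squared magnitude at
# frequency f is (1 + (f/fc)^8)^-2. The retained fraction is monotone in fc,
# so the lowest admissible cutoff is found by bisection on the periodogram;
# the cumulative-periodogram quantile is a lower bound used to bracket it.
power_cutoff <- function(values, rate, power_fraction, order = 4L) {
  x <- values - mean(values)
  n <- length(x)
  spec <- Mod(fft(x))^2
  nfreq <- floor(n / 2)
  freq <- (1:nfreq) * rate / n
  pow <- spec[2:(nfreq + 1)]          # drop the (zero) DC bin
  total <- sum(pow)
  if (total == 0) return(0)
  retained <- function(fc) {
    h2 <- 1 / (1 + (freq / fc)^(2 * order))
    sum(h2^2 * pow) / total           # zero-phase: filter applied twice
  }
  cum <- cumsum(pow) / total
  lo <- freq[which(cum >= power_fraction)[1]]
  if (is.na(lo)) lo <- freq[nfreq]
  if (retained(lo) >= power_fraction) return(lo)
  hi <- rate                          # above Nyquist; caller handles that case
  while (retained(hi) < power_fraction) hi <- 2 * hi
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (retained(mid) >= power_fraction) hi <- mid else lo <- mid
  }
  hi
}

#' Adaptive low-pass Butterworth filter
#'
#' Removes measurement artefacts while keeping essentially all of the
#' signal's power: the cutoff is chosen per series as the lowest frequency at
#' which the cumulative periodogram of the mean-removed signal reaches
#' `power_fraction` (default 99.99%) of the total power *after* the
#' forward-backward fourth-order Butterworth pass (so a spectral line just
#' below the cutoff is not clipped by the filter roll-off); the filter is
#' applied forward and backward (zero phase, so cycle timing is not biased).
#' The series is reflect-padded before filtering to suppress edge
#' transients.
#'
#' @param x A `gait_signal` (or coercible, see [as_gait_signal()]).
#' @param power_fraction Fraction of total power to retain, in (0, 1).
#' @param rate Rate for bare numeric `x`.
#' @return The filtered `gait_signal`, with attributes `cutoff_hz` (chosen
#'   cutoff) and `filtered` (FALSE when the cutoff reached Nyquist and the
#'   input was returned unchanged, with a warning).
#' @examples
#' s <- gait_signal(sin(2 * pi * 1.7 * seq(0, 10, by = 1 / 120)), rate = 120)
#' f <- adaptive_lowpass(s)
#' attr(f, "cutoff_hz")
#' @export
adaptive_lowpass <- function(x, power_fraction = 0.9999, rate = NULL) {
  x <- as_gait_signal(x, rate = rate)
  if (power_fraction <= 0 || power_fraction >= 1) {
    abort("`power_fraction` must be in (0, 1).")
  }
  order <- 4L
  if (nrow(x) < 8L * order) {
    abort(sprintf("signal too short to filter: need >= %d samples.", 8L * order))
  }
  fs <- signal_rate(x)
  nyquist <- fs / 2
  cutoff <- power_cutoff(x$value, fs, power_fraction)
  if (cutoff >= 0.99 * nyquist) {
    warn(sprintf("cutoff %.3g Hz reaches Nyquist (%.3g Hz); returning input unchanged",
                 cutoff, nyquist))
    out <- restore_signal(x$value, x)
    attr(out, "cutoff_hz") <- cutoff
    attr(out, "filtered") <- FALSE
    return(out)
  }
  bf <- signal::butter(order, cutoff / nyquist, type = "low")
  # reflect-pad so short test signals are not dominated by edge transients
  v <- x$value
  npad <- min(nrow(x) - 1L, max(3L * round(fs / max(cutoff, 1e-6)), 3L * order))
  padded <- c(2 * v[1] - rev(v[2:(npad + 1)]),
              v,
              2 * v[length(v)] - rev(v[(length(v) - npad):(length(v) - 1)]))
  filt <- signal::filtfilt(bf, padded)
  out <- restore_signal(filt[(npad + 1):(npad + length(v))], x)
  attr(out, "cutoff_hz") <- cutoff
  attr(out, "filtered") <- TRUE
  out
}

#' Cubic-spline upsampling
#'
#' Interpolates a uniformly sampled signal with a cubic spline (Forsythe end
#' conditions, so cubic polynomials are reproduced exactly) on a grid
#' `factor` times denser (default 10, e.g. 120 Hz motion capture to
#' 1200 Hz). Original samples are reproduced exactly at their own time
#' stamps.
#'
#' @param x A `gait_signal` (or coercible).
#' @param factor Integer upsampling factor (>= 1).
#' @param rate Rate for bare numeric `x`.
#' @return A `gait_signal` at `factor` times the input rate.
#' @examples
#' s <- gait_signal(sin(seq(0, 5, by = 1 / 120)), rate = 120)
#' u <- upsample_spline(s, 10)
#' signal_rate(u)
#' @export
upsample_spline <- function(x, factor = 10, rate = NULL) {
  x <- as_gait_signal(x, rate = rate)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    abort("`factor` must be a whole number >= 1.")
  }
  factor <- as.integer(factor)
  if (nrow(x) < 4L) abort("need at least 4 samples for cubic-spline upsampling.")
  if (factor == 1L) return(x)
  fs <- signal_rate(x)
  n_out <- (nrow(x) - 1L) * factor + 1L
  t_out <- x$time_s[1] + (seq_len(n_out) - 1) / (fs * factor)
  v_out <- spline(x$time_s, x$value, method = "fmm", xout = t_out)$y
  gait_signal(v_out, rate = fs * factor, t0 = x$time_s[1],
              unit = attr(x, "unit"))
}

#' Finite-difference derivative
#'
#' Central differences in the interior, one-sided differences at the two
#' edges, scaled by the sampling rate. Applied to the upsampled COM position
#' this yields the vertical velocity `P = dQ/dt`.
#'
#' @param x A `gait_signal` (or coercible).
#' @param rate Rate for bare numeric `x`.
#' @return A `gait_signal` of the same length; the unit gains "/s".
#' @examples
#' s <- gait_signal(seq(0, 1, by = 0.01), rate = 100)
#' d <- differentiate(s) # constant slope 1
#' @export
differentiate <- function(x, rate = NULL) {
  x <- as_gait_signal(x, rate = rate)
  n <- nrow(x)
  if (n < 3L) abort("need at least 3 samples to differentiate.")
  fs <- signal_rate(x)
  v <- x$value
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) * fs
  d[n] <- (v[n] - v[n - 1]) * fs
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2
  unit <- attr(x, "unit") %||% "?"
  restore_signal(d, x, unit = paste0(unit, "/s"))
}

#' Marker-to-trajectory processing pipeline
#'
#' Chains the full kinematic pre-processing: marker averaging
#' ([com_from_markers()]), adaptive zero-phase low-pass filtering
#' ([adaptive_lowpass()]), cubic-spline upsampling ([upsample_spline()],
#' default x10), and finite-difference velocity ([differentiate()]).
#'
#' @param markers A marker set (see [com_from_markers()]).
#' @param power_fraction Power fraction for the adaptive filter.
#' @param factor Upsampling factor.
#' @return A [com_trajectory()] with attribute `cutoff_hz`.
#' @examples
#' sim <- simulate_oscillator(osc_config(duration = 30, seed = 1))
#' mk <- synthesize_markers(sim, seed = 2)
#' traj <- process_markers(mk)
#' @export
process_markers <- function(markers, power_fraction = 0.9999, factor = 10) {
  q_raw <- com_from_markers(markers)
  q_filt <- adaptive_lowpass(q_raw, power_fraction = power_fraction)
  q_up <- upsample_spline(q_filt, factor = factor)
  p <- differentiate(q_up)
  out <- com_trajectory(q_up, p)
  attr(out, "cutoff_hz") <- attr(q_filt, "cutoff_hz")
  out
}
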