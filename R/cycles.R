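# Gait-cycle segmentation and per-cycle energetics.
#
# A step is the stretch of samples between two successive maxima of Q(t); a
# gait cycle is two consecutive steps. For each cycle i we record its
# duration T_i, frequency f_i = 1/T_i and mean kinetic energy per unit mass
# Ekbar_i = <P^2/2>. The adiabatic invariant is I = Ekm / (pi * fm) with
# Ekm, fm the across-cycle means; the model predicts Ekbar_i/Ekm = f_i/fm.

# Strict local maxima of a numeric vector.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

# Topographic prominence of each candidate peak: descend on each side until a
# higher sample is met (or the series edge); the base is the lowest valley on
# that path and prominence = peak - max(left base, right base).
peak_prominence <- function(v, pk) {
  np <- length(pk)
  pv <- v[pk]
  if (np == 0L) return(numeric(0))
  valley <- numeric(max(np - 1L, 0L))
  if (np > 1L) {
    for (i in seq_len(np - 1L)) valley[i] <- min(v[pk[i]:pk[i + 1L]])
  }
  left_edge <- min(v[1:pk[1L]])
  right_edge <- min(v[pk[np]:length(v)])
  prom <- numeric(np)
  for (i in seq_len(np)) {
    lbase <- Inf
    j <- i - 1L
    repeat {
      if (j < 1L) { lbase <- min(lbase, left_edge); break }
      lbase <- min(lbase, valley[j])
      if (pv[j] > pv[i]) break
      j <- j - 1L
    }
    rbase <- Inf
    j <- i
    repeat {
      if (j > np - 1L) { rbase <- min(rbase, right_edge); break }
      rbase <- min(rbase, valley[j])
      if (pv[j + 1L] > pv[i]) break
      j <- j + 1L
    }
    prom[i] <- pv[i] - max(lbase, rbase)
  }
  prom
}

#' Detect steps as maxima of the COM vertical position
#'
#' Finds the local maxima of `Q(t)` that delimit steps. Candidate maxima are
#' filtered by topographic prominence (at least `prominence_frac` of the
#' interquartile range of Q, so measurement ripple is ignored) and by a
#' minimum separation equal to `min_sep_frac` times the median inter-peak
#' interval of an unconstrained first pass (closely spaced spurious maxima
#' are resolved in favour of the higher peak).
#'
#' @param x A [com_trajectory()] or a Q `gait_signal`.
#' @param min_sep_frac Minimum peak separation as a fraction of the median
#'   first-pass inter-peak interval (default 0.5).
#' @param prominence_frac Prominence floor as a fraction of IQR(Q)
#'   (default 0.1).
#' @return Integer vector of sample indices of the retained maxima.
#' @examples
#' traj <- simulate_oscillator(osc_config(duration = 20, seed = 1))
#' peaks <- detect_steps(traj)
#' @export
detect_steps <- function(x, min_sep_frac = 0.5, prominence_frac = 0.1) {
  v <- if (inherits(x, "com_trajectory")) x$q_m else signal_values(x)
  pk <- local_maxima(v)
  if (length(pk) < 3L) {
    abort("step segmentation failed: fewer than 3 maxima in Q(t).")
  }
  iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE))
  if (iqr > 0 && prominence_frac > 0) {
    prom <- peak_prominence(v, pk)
    pk <- pk[prom >= prominence_frac * iqr]
  }
  if (length(pk) >= 2L && min_sep_frac > 0) {
    min_sep <- min_sep_frac * median(diff(pk))
    # greedy acceptance from the highest peak down
    ord <- pk[order(v[pk], decreasing = TRUE)]
    keep <- integer(0)
    for (p in ord) {
      if (length(keep) == 0L || min(abs(keep - p)) >= min_sep) keep <- c(keep, p)
    }
    pk <- sort(keep)
  }
  if (length(pk) < 3L) {
    abort("step segmentation failed: fewer than 3 maxima survive filtering.")
  }
  pk
}

#' Pair steps into gait cycles
#'
#' A gait cycle spans two consecutive steps: cycles run over maxima
#' (1 -> 3), (3 -> 5), ... starting at the first detected maximum; a trailing
#' unpaired step is discarded.
#'
#' @param peaks Integer vector of step maxima indices (from
#'   [detect_steps()]), at least 3.
#' @return Tibble with columns `cycle`, `start_idx`, `end_idx`.
#' @examples
#' segment_cycles(c(10, 20, 30, 40, 50))
#' @export
segment_cycles <- function(peaks) {
  peaks <- sort(as.integer(peaks))
  if (length(peaks) < 3L) abort("need at least 3 step maxima to form a cycle.")
  n_cyc <- (length(peaks) - 1L) %/% 2L
  starts <- peaks[2L * seq_len(n_cyc) - 1L]
  ends <- peaks[2L * seq_len(n_cyc) + 1L]
  tibble(cycle = seq_len(n_cyc), start_idx = starts, end_idx = ends)
}

#' Per-cycle duration, frequency and mean kinetic energy
#'
#' For each cycle, `T_i` is the spanned time, `f_i = 1/T_i`, and
#' `Ekbar_i` is the arithmetic time average of `P^2/2` over the cycle's
#' samples (mass scale 1, so units are J/kg).
#'
#' @param traj A [com_trajectory()].
#' @param cycles Cycle boundary tibble from [segment_cycles()].
#' @return `cycles` with columns `t_s`, `f_hz`, `ekbar_jkg` added.
#' @export
cycle_energetics <- function(traj, cycles) {
  traj <- as_com_trajectory(traj)
  rate <- attr(traj, "rate")
  if (nrow(cycles) < 1L) abort("no cycles to evaluate.")
  span <- cycles$end_idx - cycles$start_idx
  if (any(span < 8L)) {
    abort("cycle spans fewer than 8 samples; segmentation is degenerate.")
  }
  # cumulative kinetic energy lets every cycle average be O(1);
  # the average is over the half-open span [start, end)
  cs <- c(0, cumsum(0.5 * traj$p_mps^2))
  ek <- (cs[cycles$end_idx] - cs[cycles$start_idx]) / span
  dplyr::mutate(cycles,
                t_s = span / rate,
                f_hz = rate / span,
                ekbar_jkg = ek)
}

#' Gait-cycle table with the adiabatic invariant
#'
#' Segments a COM trajectory into gait cycles (unless boundaries are given)
#' and assembles the per-cycle records together with the across-cycle
#' aggregates: `Ekm = mean(Ekbar_i)`, `fm = mean(f_i)`, the adiabatic
#' invariant `I = Ekm / (pi fm)` and `piI = pi I`. Normalized pairs
#' `f_rel = f_i/fm`, `ek_rel = Ekbar_i/Ekm` are included; the oscillator
#' model predicts they fall on the line `ek_rel = f_rel` (slope 1, zero
#' intercept).
#'
#' @param traj A [com_trajectory()].
#' @param cycles Optional cycle boundaries (from [segment_cycles()]);
#'   computed with default settings when omitted.
#' @param ... Passed to [detect_steps()] when `cycles` is NULL.
#' @return A tibble of class `gait_cycle_table` with one row per cycle and
#'   aggregate attributes; see [glance.gait_cycle_table()].
#' @examples
#' traj <- simulate_oscillator(osc_config(duration = 60, seed = 1))
#' tab <- invariant_table(traj)
#' glance(tab)
#' @export
invariant_table <- function(traj, cycles = NULL, ...) {
  traj <- as_com_trajectory(traj)
  if (is.null(cycles)) {
    cycles <- segment_cycles(detect_steps(traj, ...))
  }
  if (nrow(cycles) < 2L) abort("need at least 2 gait cycles.")
  tab <- cycle_energetics(traj, cycles)
  ekm <- mean(tab$ekbar_jkg)
  fm <- mean(tab$f_hz)
  inv <- ekm / (pi * fm)
  tab <- dplyr::mutate(tab,
                       f_rel = .data$f_hz / fm,
                       ek_rel = .data$ekbar_jkg / ekm)
  structure(tab,
            class = c("gait_cycle_table", class(tab)),
            ekm_jkg = ekm, fm_hz = fm,
            invariant_jskg = inv, pi_invariant_jskg = pi * inv)
}

#' One-row summary of a gait-cycle table
#'
#' @param x A `gait_cycle_table` from [invariant_table()].
#' @param ... Unused.
#' @return Tibble with `n_cycles`, `ekm_jkg`, `fm_hz`, `invariant_jskg`
#'   (`I`), `pi_invariant_jskg` (`pi I`, the form in which the invariant is
#'   usually reported), and the mean stride interval `si_s = 1/fm`.
#' @export
glance.gait_cycle_table <- function(x, ...) {
  tibble(
    n_cycles = nrow(x),
    ekm_jkg = attr(x, "ekm_jkg"),
    fm_hz = attr(x, "fm_hz"),
    si_s = 1 / attr(x, "fm_hz"),
    invariant_jskg = attr(x, "invariant_jskg"),
    pi_invariant_jskg = attr(x, "pi_invariant_jskg")
  )
}

#' Averaged phase-space attractor
#'
#' Each gait cycle is normalized to unit duration, resampled with a cubic
#' spline at `bins` equally spaced points, and the mean and standard
#' deviation of `Q` and `P` are taken bin-wise across cycles. The mean loop
#' is the participant's limit-cycle attractor in `(Q, P)` phase space; its
#' enclosed area equals `2 pi I` for the noiseless oscillator.
#'
#' @param traj A [com_trajectory()].
#' @param cycles Optional cycle boundaries; computed when omitted.
#' @param bins Number of phase bins (default 1200).
#' @param ... Passed to [detect_steps()] when `cycles` is NULL.
#' @return A tibble of class `gait_attractor` with columns `phase` (0-1),
#'   `q_mean`, `q_sd`, `p_mean`, `p_sd` and attribute `n_cycles`.
#' @examples
#' traj <- simulate_oscillator(osc_config(duration = 60, seed = 1))
#' att <- mean_attractor(traj)
#' @export
mean_attractor <- function(traj, cycles = NULL, bins = 1200, ...) {
  traj <- as_com_trajectory(traj)
  if (is.null(cycles)) {
    cycles <- segment_cycles(detect_steps(traj, ...))
  }
  if (nrow(cycles) < 2L) abort("need at least 2 gait cycles for an attractor.")
  phase <- seq(0, 1, length.out = bins)
  resample <- function(s, e, v) {
    idx <- s:e
    u <- (idx - s) / (e - s)
    spline(u, v[idx], method = "fmm", xout = phase)$y
  }
  qs <- purrr::map2(cycles$start_idx, cycles$end_idx, resample, v = traj$q_m)
  ps <- purrr::map2(cycles$start_idx, cycles$end_idx, resample, v = traj$p_mps)
  qm <- do.call(cbind, qs)
  pm <- do.call(cbind, ps)
  sd_row <- function(m) apply(m, 1, sd)
  out <- tibble(
    phase = phase,
    q_mean = rowMeans(qm), q_sd = sd_row(qm),
    p_mean = rowMeans(pm), p_sd = sd_row(pm)
  )
  structure(out,
            class = c("gait_attractor", class(out)),
            n_cycles = nrow(cycles))
}

#' Enclosed area of an attractor loop
#'
#' Shoelace area of the mean `(Q, P)` loop. For the noiseless harmonic
#' oscillator the loop is an ellipse with semi-axes `A` (position) and
#' `omega A` (velocity), so the enclosed area is `pi omega A^2`, i.e.
#' `2 pi J` with `J = E / omega` the classical action.
#'
#' @param attractor A `gait_attractor`.
#' @return Absolute enclosed area (m^2/s).
#' @export
attractor_area <- function(attractor) {
  q <- attractor$q_mean
  p <- attractor$p_mean
  n <- length(q)
  j <- c(2:n, 1)
  abs(sum(q * p[j] - q[j] * p)) / 2
}
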