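#' Uniformly sampled scalar signals
#'
#' The kinematics pipeline works on evenly sampled scalar time series (the
#' vertical center-of-mass position `Q(t)` in metres, its velocity
#' `P(t) = dQ/dt` in m/s). These are stored as tibbles with columns `time_s`
#' and `value` plus a `rate` attribute (Hz), so they pipe cleanly through
#' dplyr and ggplot2 while every operation can rely on a constant sampling
#' interval.
#'
#' @param value Numeric vector of samples.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param unit Unit label carried along for printing ("m", "m/s", ...).
#'
#' @return A tibble of class `gait_signal` with columns `time_s`, `value`.
#' @examples
#' s <- gait_signal(sin(2 * pi * seq(0, 2, by = 1 / 120)), rate = 120)
#' signal_rate(s)
#' @export
gait_signal <- function(value, rate, t0 = 0, unit = "m") {
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  value <- as.double(value)
  if (anyNA(value)) {
    abort(sprintf("signal contains missing samples (first at index %d); fill gaps upstream",
                  which(is.na(value))[1]))
  }
  out <- tibble(
    time_s = t0 + (seq_along(value) - 1) / rate,
    value = value
  )
  structure(out,
            class = c("gait_signal", class(out)),
            rate = as.double(rate),
            t0 = as.double(t0),
            unit = unit)
}

#' Coerce to a uniform signal
#'
#' Accepts a numeric vector (with `rate` supplied), a `gait_signal`, or a data
#' frame with columns `time_s` and `value` (rate inferred from the time stamps
#' and checked for uniformity).
#'
#' @param x Object to coerce.
#' @param rate Sampling rate in Hz; required for bare numeric vectors.
#' @param unit Unit label, see [gait_signal()].
#' @return A `gait_signal` tibble.
#' @export
as_gait_signal <- function(x, rate = NULL, unit = "m") {
  if (inherits(x, "gait_signal")) return(x)
  if (is.numeric(x)) {
    if (is.null(rate)) abort("`rate` is required when `x` is a bare numeric vector.")
    return(gait_signal(x, rate = rate, unit = unit))
  }
  if (is.data.frame(x)) {
    if (!all(c("time_s", "value") %in% names(x))) {
      abort("data frame signals need columns `time_s` and `value`.")
    }
    dt <- diff(x$time_s)
    if (length(dt) < 1L) abort("signal needs at least 2 samples to infer a rate.")
    if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
      abort("`time_s` is not uniformly sampled.")
    }
    return(gait_signal(x$value, rate = 1 / dt[1], t0 = x$time_s[1], unit = unit))
  }
  abort("cannot interpret `x` as a uniform signal.")
}

#' Sampling rate of a signal
#' @param x A `gait_signal` (or data frame with a uniform `time_s` column).
#' @return Rate in Hz.
#' @export
signal_rate <- function(x) {
  r <- attr(x, "rate")
  if (!is.null(r)) return(r)
  as_gait_signal(x) |> attr("rate")
}

signal_values <- function(x) {
  if (is.numeric(x)) as.double(x) else as_gait_signal(x)$value
}

#' @export
print.gait_signal <- function(x, ...) {
  cat(sprintf("# Uniform signal: %d samples at %g Hz (%s)\n",
              nrow(x), attr(x, "rate"), attr(x, "unit") %||% "?"))
  NextMethod()
}

# Rebuild class/attrs after dplyr operations that strip them.
restore_signal <- function(values, template, unit = NULL) {
  gait_signal(values,
              rate = attr(template, "rate"),
              t0 = attr(template, "t0") %||% template$time_s[1],
              unit = unit %||% attr(template, "unit"))
}

#' Center-of-mass phase-space trajectory
#'
#' Bundles position `Q` (m) and velocity `P = dQ/dt` (m/s) on a shared uniform
#' time grid. This is the object the cycle-segmentation layer consumes; it is
#' produced either by [simulate_oscillator()] or by [process_markers()].
#'
#' @param q A `gait_signal` holding Q in metres (or numeric with `rate`).
#' @param p Optional matching velocity signal; computed with
#'   [differentiate()] when omitted.
#' @param rate Sampling rate, needed only when `q` is a bare numeric vector.
#' @return A tibble of class `com_trajectory` with columns `time_s`, `q_m`,
#'   `p_mps` and a `rate` attribute.
#' @export
com_trajectory <- function(q, p = NULL, rate = NULL) {
  q <- as_gait_signal(q, rate = rate, unit = "m")
  if (is.null(p)) {
    p <- differentiate(q)
  } else {
    p <- as_gait_signal(p, rate = signal_rate(q), unit = "m/s")
    if (nrow(p) != nrow(q)) abort("`q` and `p` must have the same length.")
  }
  out <- tibble(time_s = q$time_s, q_m = q$value, p_mps = p$value)
  structure(out,
            class = c("com_trajectory", class(out)),
            rate = signal_rate(q))
}

as_com_trajectory <- function(x) {
  if (inherits(x, "com_trajectory")) return(x)
  if (is.data.frame(x) && all(c("time_s", "q_m", "p_mps") %in% names(x))) {
    q <- as_gait_signal(tibble(time_s = x$time_s, value = x$q_m), unit = "m")
    p <- gait_signal(x$p_mps, rate = signal_rate(q), t0 = x$time_s[1], unit = "m/s")
    return(com_trajectory(q, p))
  }
  if (inherits(x, "gait_signal")) return(com_trajectory(x))
  abort("expected a `com_trajectory`, a Q/P data frame, or a Q signal.")
}

#' @export
print.com_trajectory <- function(x, ...) {
  cat(sprintf("# COM trajectory: %d samples at %g Hz\n", nrow(x), attr(x, "rate")))
  NextMethod()
}
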