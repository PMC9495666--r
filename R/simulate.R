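#' Configuration for the stochastic oscillator model of COM motion
#'
#' The vertical center-of-mass excursion during steady walking is modelled as
#' a harmonic oscillator whose angular frequency fluctuates slowly around a
#' mean: `Qddot = -omega(t)^2 Q` with `omega(t) = omega0 * (1 + epsilon *
#' xi(t))` and `xi(t)` unit-variance coloured noise. The slow fluctuation
#' stands in for physiological noise; under it the action `Ekbar / (pi f)` of
#' each cycle is an adiabatic invariant, so per-cycle mean kinetic energy and
#' cycle frequency stay proportional even though both drift.
#'
#' Defaults emulate comfortable treadmill walking: the COM bobs once per step
#' at ~1.7 Hz (two steps per ~1.18 s gait cycle) with a 2 cm half-range, and
#' the fractional frequency noise has the magnitude of observed
#' stride-interval coefficients of variation (~0.026).
#'
#' @param omega0 Mean angular frequency of the COM oscillation (rad/s).
#' @param epsilon Fractional frequency noise magnitude (dimensionless,
#'   `0 <= epsilon << 1`).
#' @param tau Correlation time of the noise in seconds (> 0); "slow" means
#'   several oscillation periods.
#' @param amplitude0 Initial COM half-range in metres.
#' @param duration Simulated time in seconds (at least 10 periods).
#' @param dt Integration step in seconds; must resolve the oscillation with
#'   at least 20 steps per period.
#' @param seed Integer seed for the noise realization (NULL = use current RNG).
#' @param noise `"ou"` for an Ornstein-Uhlenbeck process, `"percycle"` for a
#'   piecewise-constant draw renewed once per oscillation period.
#' @param integrator `"rk4"` (fixed-step 4th-order Runge-Kutta, default) or
#'   `"leapfrog"` (symplectic).
#'
#' @return A list of class `osc_config`.
#' @examples
#' cfg <- osc_config(duration = 30, seed = 1)
#' traj <- simulate_oscillator(cfg)
#' @export
osc_config <- function(omega0 = 2 * pi * 1.7,
                       epsilon = 0.026,
                       tau = 12,
                       amplitude0 = 0.02,
                       duration = 600,
                       dt = 0.005,
                       seed = NULL,
                       noise = c("ou", "percycle"),
                       integrator = c("rk4", "leapfrog")) {
  check_number(omega0, "omega0", lower = 0, strict_lower = TRUE)
  check_number(epsilon, "epsilon", lower = 0)
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  check_number(amplitude0, "amplitude0", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  period <- 2 * pi / omega0
  if (dt >= period / 20) {
    abort(sprintf("`dt` must resolve the oscillation: need dt < %.4g s (20 steps per period).",
                  period / 20))
  }
  if (duration < 10 * period) {
    abort(sprintf("`duration` must cover at least 10 periods (>= %.3g s).", 10 * period))
  }
  structure(
    list(omega0 = omega0, epsilon = epsilon, tau = tau,
         amplitude0 = amplitude0, duration = duration, dt = dt,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         noise = match.arg(noise), integrator = match.arg(integrator)),
    class = "osc_config")
}

#' Ornstein-Uhlenbeck noise with unit stationary variance
#'
#' Mean-reverting Gaussian noise with autocorrelation `exp(-lag / tau)`, used
#' as the slow frequency perturbation `xi(t)`. The exact discretization
#' `x[k+1] = a x[k] + sqrt(1 - a^2) z[k]` with `a = exp(-dt / tau)` is used,
#' so samples are draws from the stationary process at any `dt`.
#'
#' @param n Number of samples (>= 1).
#' @param dt Sampling interval in seconds (> 0).
#' @param tau Correlation time in seconds (> 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`, zero mean and unit variance in
#'   distribution.
#' @examples
#' x <- ou_noise(1000, dt = 0.01, tau = 1, seed = 1)
#' @export
ou_noise <- function(n, dt, tau, seed = NULL) {
  check_number(n, "n", lower = 1)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  n <- as.integer(n)
  with_seed_opt(seed, {
    a <- exp(-dt / tau)
    innov_sd <- sqrt(1 - a^2)
    z <- rnorm(n)
    x <- numeric(n)
    x[1] <- z[1]
    if (n > 1L) {
      for (k in 2:n) x[k] <- a * x[k - 1] + innov_sd * z[k]
    }
    x
  })
}

# Noise on the half-step grid (2*nstep + 1 points at dt/2) so RK4 stages see
# the mid-step frequency exactly.
half_grid_noise <- function(cfg, nstep) {
  nhalf <- 2L * nstep + 1L
  if (cfg$epsilon == 0) return(numeric(nhalf))
  if (cfg$noise == "ou") {
    ou_noise(nhalf, dt = cfg$dt / 2, tau = cfg$tau, seed = cfg$seed)
  } else {
    # one standard-normal draw per oscillation period, held constant
    period <- 2 * pi / cfg$omega0
    per_half_step <- cfg$dt / 2
    idx <- pmin(floor((seq_len(nhalf) - 1) * per_half_step / period) + 1,
                ceiling(nhalf * per_half_step / period) + 1)
    draws <- with_seed_opt(cfg$seed, rnorm(max(idx)))
    draws[idx]
  }
}

#' Simulate the frequency-modulated oscillator
#'
#' Integrates `Qddot = -omega(t)^2 Q`, `omega(t) = omega0 (1 + epsilon
#' xi(t))`, from `Q(0) = amplitude0`, `P(0) = 0`, with a fixed-step RK4 (or
#' leapfrog) scheme. With `epsilon = 0` the total energy `P^2/2 +
#' omega0^2 Q^2 / 2` is conserved to better than one part in 1e6 over
#' hundreds of cycles at the default step.
#'
#' @param cfg An [osc_config()].
#' @return A [com_trajectory()] tibble (`time_s`, `q_m`, `p_mps`) with
#'   attributes `rate` (1/dt) and `config`.
#' @examples
#' traj <- simulate_oscillator(osc_config(duration = 20, seed = 7))
#' @export
simulate_oscillator <- function(cfg) {
  if (!inherits(cfg, "osc_config")) abort("`cfg` must be an `osc_config`.")
  nstep <- floor(cfg$duration / cfg$dt)
  xi <- half_grid_noise(cfg, nstep)
  omega_half <- cfg$omega0 * (1 + cfg$epsilon * xi)
  states <- switch(cfg$integrator,
    rk4      = .integrate_rk4(omega_half, cfg$amplitude0, 0, cfg$dt),
    leapfrog = .integrate_leapfrog(omega_half, cfg$amplitude0, 0, cfg$dt))
  q <- gait_signal(states[, 1], rate = 1 / cfg$dt, unit = "m")
  p <- gait_signal(states[, 2], rate = 1 / cfg$dt, unit = "m/s")
  out <- com_trajectory(q, p)
  attr(out, "config") <- cfg
  out
}

#' Fractional Gaussian noise
#'
#' Exact-covariance fGn via circulant embedding (Davies-Harte). The target
#' autocovariance is `gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2`
#' (unit variance). If the circulant spectrum has negative eigenvalues (it
#' does not for fGn at practical lengths) they are truncated to zero and the
#' series rescaled to unit variance, with a message.
#'
#' @param n Series length (>= 2).
#' @param hurst Hurst exponent in (0, 1); 0.5 gives white noise.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` with zero mean, unit variance in
#'   distribution, and Hurst exponent `hurst`.
#' @examples
#' x <- fgn(512, hurst = 0.8, seed = 42)
#' @export
fgn <- function(n, hurst, seed = NULL) {
  check_number(n, "n", lower = 2)
  check_number(hurst, "hurst", lower = 0, strict_lower = TRUE)
  if (hurst >= 1) abort("`hurst` must be in (0, 1).")
  n <- as.integer(n)
  k <- 0:n
  gam <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
  # first row of the 2n-circulant: gamma(0..n), then gamma(n-1..1)
  r <- c(gam, rev(gam[2:n]))
  m <- length(r)                       # m = 2n
  lam <- Re(fft(r))
  if (min(lam) < -1e-8 * max(lam)) {
    inform("circulant embedding not nonnegative definite; truncating negative eigenvalues")
  }
  lam <- pmax(lam, 0)
  x <- with_seed_opt(seed, {
    w <- complex(length.out = m)
    z <- rnorm(m + 2)                   # 2 real + (m/2 - 1) complex pairs
    w[1] <- sqrt(lam[1] / m) * z[1]
    w[m / 2 + 1] <- sqrt(lam[m / 2 + 1] / m) * z[2]
    j <- 2:(m / 2)
    re <- z[2 * j - 1]
    im <- z[2 * j]
    w[j] <- sqrt(lam[j] / (2 * m)) * complex(real = re, imaginary = im)
    w[m + 2 - j] <- Conj(w[j])
    Re(fft(w))[seq_len(n)]
  })
  # exact embedding has stationary variance sum(lam)/m == gamma(0) == 1;
  # after truncation this renormalizes back to unit variance
  x / sqrt(sum(lam) / m)
}

#' Configuration for synthetic stride-interval series
#'
#' Defaults reproduce the statistics of comfortable overground-paced
#' treadmill walking in healthy young adults: mean stride interval 1.184 s,
#' coefficient of variation 0.026, and persistent fractal structure with
#' Hurst exponent 0.85 (the healthy band is roughly 0.7-0.9; 0.5 is
#' uncorrelated).
#'
#' @param n_strides Number of strides (>= 64).
#' @param hurst_target Target Hurst exponent in (0, 1).
#' @param mean_si Mean stride interval in seconds (> 0).
#' @param cv_target Coefficient of variation (>= 0).
#' @param seed Optional integer seed.
#' @return A list of class `stride_config`.
#' @export
stride_config <- function(n_strides = 512,
                          hurst_target = 0.85,
                          mean_si = 1.184,
                          cv_target = 0.026,
                          seed = NULL) {
  check_number(n_strides, "n_strides", lower = 64)
  check_number(hurst_target, "hurst_target", lower = 0, strict_lower = TRUE)
  if (hurst_target >= 1) abort("`hurst_target` must be in (0, 1).")
  check_number(mean_si, "mean_si", lower = 0, strict_lower = TRUE)
  check_number(cv_target, "cv_target", lower = 0)
  # a Gaussian series with mass beyond zero cannot represent stride times
  if (cv_target > 0 && stats::pnorm(0, mean_si, cv_target * mean_si) > 1e-3) {
    abort("`cv_target` implies non-positive strides with probability > 1e-3.")
  }
  structure(
    list(n_strides = as.integer(n_strides), hurst_target = hurst_target,
         mean_si = mean_si, cv_target = cv_target,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "stride_config")
}

#' Generate a fractal stride-interval series
#'
#' Fractional Gaussian noise with the configured Hurst exponent, rescaled to
#' the requested mean and coefficient of variation. Any stride below a
#' quarter of the mean (vanishingly rare at physiological CVs) is clipped to
#' that floor, with a message.
#'
#' @param cfg A [stride_config()].
#' @return A tibble of class `stride_series` with columns `cycle_index`,
#'   `stride_s` and a `config` attribute.
#' @examples
#' strides <- generate_fgn_strides(stride_config(n_strides = 128, seed = 3))
#' @export
generate_fgn_strides <- function(cfg) {
  if (!inherits(cfg, "stride_config")) abort("`cfg` must be a `stride_config`.")
  x <- if (cfg$cv_target == 0) {
    rep(0, cfg$n_strides)
  } else {
    fgn(cfg$n_strides, cfg$hurst_target, seed = cfg$seed)
  }
  strides <- cfg$mean_si + cfg$cv_target * cfg$mean_si * x
  floor_s <- cfg$mean_si / 4
  n_clip <- sum(strides < floor_s)
  if (n_clip > 0) {
    inform(sprintf("clipped %d stride(s) at the %.3g s floor", n_clip, floor_s))
    strides <- pmax(strides, floor_s)
  }
  out <- tibble(cycle_index = seq_len(cfg$n_strides), stride_s = strides)
  structure(out,
            class = c("stride_series", class(out)),
            config = cfg)
}

#' Synthesize pelvic marker trajectories from a COM signal
#'
#' Emulates optoelectronic acquisition of the four Plug-In-Gait pelvic
#' markers (RASI, LASI, RPSI, LPSI): each marker is the COM vertical
#' trajectory in millimetres plus a constant vertical offset and i.i.d.
#' Gaussian measurement noise, resampled (cubic spline) to the camera rate.
#' The four offsets sum to zero, so averaging the markers recovers the COM.
#'
#' @param q COM vertical position: a `gait_signal` in metres, a
#'   [com_trajectory()], or a numeric vector with `rate`.
#' @param rate_out Camera sampling rate in Hz (default 120).
#' @param marker_noise_sd Per-marker measurement noise SD in millimetres.
#' @param offsets_mm Length-4 vector of constant marker offsets (mm), summed
#'   to zero internally by removing their mean. Anterior markers sit higher
#'   than posterior ones by default.
#' @param baseline_mm Constant pelvis height added to all markers (mm;
#'   default 0 so the marker mean recovers `Q` exactly — a realistic
#'   standing height, e.g. 1000, only shifts the recovered signal by a
#'   constant and is irrelevant to velocities and cycle timing).
#' @param seed Optional integer seed for the noise.
#' @param rate Rate for bare numeric `q`.
#' @return A tibble of class `marker_set` with columns `time_s`,
#'   `RASI_z_mm`, `LASI_z_mm`, `RPSI_z_mm`, `LPSI_z_mm`.
#' @examples
#' traj <- simulate_oscillator(osc_config(duration = 20, seed = 1))
#' mk <- synthesize_markers(traj, seed = 2)
#' @export
synthesize_markers <- function(q, rate_out = 120, marker_noise_sd = 0.5,
                               offsets_mm = c(25, 25, -25, -25),
                               baseline_mm = 0, seed = NULL, rate = NULL) {
  if (inherits(q, "com_trajectory")) {
    q <- gait_signal(q$q_m, rate = attr(q, "rate"), t0 = q$time_s[1], unit = "m")
  }
  q <- as_gait_signal(q, rate = rate, unit = "m")
  check_number(rate_out, "rate_out", lower = 0, strict_lower = TRUE)
  check_number(marker_noise_sd, "marker_noise_sd", lower = 0)
  if (length(offsets_mm) != 4L) abort("`offsets_mm` must have length 4.")
  dur <- (nrow(q) - 1) / signal_rate(q)
  if (dur < 2) abort("`q` must span at least 2 s.")
  offsets_mm <- offsets_mm - mean(offsets_mm)
  t_out <- seq(q$time_s[1], q$time_s[nrow(q)], by = 1 / rate_out)
  q_mm <- splinefun(q$time_s, q$value * 1000, method = "fmm")(t_out)
  labels <- c("RASI_z_mm", "LASI_z_mm", "RPSI_z_mm", "LPSI_z_mm")
  noise <- with_seed_opt(seed, {
    matrix(rnorm(length(t_out) * 4, sd = marker_noise_sd), ncol = 4)
  })
  cols <- purrr::map(1:4, function(i) {
    baseline_mm + q_mm + offsets_mm[i] + noise[, i]
  })
  out <- tibble(time_s = t_out, !!!setNames(cols, labels))
  structure(out,
            class = c("marker_set", class(out)),
            rate = as.double(rate_out))
}
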