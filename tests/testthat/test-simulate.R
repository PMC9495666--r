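# Synthetic-data generators: OU noise, stochastic oscillator, fGn strides,
# marker synthesis.

test_that("OU noise matches its closed-form autocorrelation and is stationary", {
  x <- ou_noise(1e5, dt = 0.01, tau = 1.0, seed = 101)
  expect_equal(mean(x), 0, tolerance = 0.05)
  expect_equal(var(x), 1, tolerance = 0.1)  # ~500 effective samples
  acf100 <- cor(x[-(1:100)], head(x, -100))
  expect_lt(abs(acf100 - exp(-1)), 0.05)
  # a single sample is a stationary draw, not an error
  expect_length(ou_noise(1, dt = 0.01, tau = 1, seed = 1), 1)
})

test_that("OU noise is deterministic under a fixed seed and validates inputs", {
  expect_identical(ou_noise(500, 0.01, 2, seed = 7),
                   ou_noise(500, 0.01, 2, seed = 7))
  expect_error(ou_noise(10, 0.01, tau = 0), "tau")
  expect_error(ou_noise(10, dt = -1, tau = 1), "dt")
})

test_that("noise-free oscillator reproduces the exact harmonic solution", {
  cfg <- osc_config(omega0 = 2 * pi, epsilon = 0, amplitude0 = 0.02,
                    duration = 10, dt = 1 / 400)
  tr <- simulate_oscillator(cfg)
  expect_lt(max(abs(tr$q_m - 0.02 * cos(2 * pi * tr$time_s))), 1e-4)
  expect_lt(max(abs(tr$p_mps + 0.02 * 2 * pi * sin(2 * pi * tr$time_s))), 1e-3)
})

test_that("noise-free energy is conserved to 1e-6 over 100 cycles (RK4 gate)", {
  cfg <- osc_config(omega0 = 2 * pi, epsilon = 0, amplitude0 = 0.02,
                    duration = 100, dt = 0.005)
  tr <- simulate_oscillator(cfg)
  energy <- 0.5 * tr$p_mps^2 + 0.5 * (2 * pi)^2 * tr$q_m^2
  expect_lt((max(energy) - min(energy)) / energy[1], 1e-6)
})

test_that("leapfrog integrator has no secular energy drift", {
  cfg <- osc_config(omega0 = 2 * pi, epsilon = 0, amplitude0 = 0.02,
                    duration = 100, dt = 0.005, integrator = "leapfrog")
  tr <- simulate_oscillator(cfg)
  energy <- 0.5 * tr$p_mps^2 + 0.5 * (2 * pi)^2 * tr$q_m^2
  drift <- abs(mean(tail(energy, 1000)) - mean(head(energy, 1000))) / energy[1]
  expect_lt(drift, 1e-8)
})

test_that("without noise the per-cycle invariant is constant to 1e-3", {
  cfg <- osc_config(omega0 = 2 * pi * 0.85, epsilon = 0, amplitude0 = 0.02,
                    duration = 60, dt = 0.005)
  tab <- invariant_table(simulate_oscillator(cfg))
  inv <- tab$ekbar_jkg / (pi * tab$f_hz)
  expect_lt(diff(range(inv)) / mean(inv), 1e-3)
})

test_that("oscillator configs violating the invariants are rejected", {
  expect_error(osc_config(dt = 0.1), "dt")                   # < 20 steps/period
  expect_error(osc_config(duration = 2), "duration")         # < 10 periods
  expect_error(osc_config(epsilon = -0.1), "epsilon")
  expect_error(osc_config(tau = 0), "tau")
  expect_error(simulate_oscillator(list()), "osc_config")
})

test_that("oscillator output is bit-identical under a fixed seed", {
  cfg <- osc_config(duration = 15, epsilon = 0.03, seed = 12)
  expect_identical(simulate_oscillator(cfg), simulate_oscillator(cfg))
  cfg2 <- osc_config(duration = 15, epsilon = 0.03, seed = 13)
  expect_false(identical(simulate_oscillator(cfg)$q_m,
                         simulate_oscillator(cfg2)$q_m))
})

test_that("fGn matches the exact Cholesky construction in law", {
  # same covariance target: compare empirical autocovariances on many
  # replicates of both generators at small n
  n <- 128
  acov_emp <- function(gen) {
    reps <- vapply(1:200, gen, numeric(n))
    v <- rowMeans(reps * reps)
    l1 <- rowMeans(reps[-1, ] * reps[-n, ])
    c(mean(v), mean(l1))
  }
  a_pkg <- acov_emp(function(i) fgn(n, 0.8, seed = i))
  a_chol <- acov_emp(function(i) fgn_cholesky(n, 0.8, seed = 10000 + i))
  expect_equal(a_pkg[1], 1, tolerance = 0.1)
  expect_equal(a_chol[1], 1, tolerance = 0.1)
  expect_equal(a_pkg[2], fgn_acov(1, 0.8), tolerance = 0.1)
  expect_equal(a_pkg[2], a_chol[2], tolerance = 0.1)
})

test_that("fGn at H = 0.5 is white: lag-1 autocorrelation near zero", {
  x <- fgn(1024, 0.5, seed = 5)
  expect_lt(abs(cor(x[-1], head(x, -1))), 0.1)
  expect_identical(fgn(256, 0.7, seed = 3), fgn(256, 0.7, seed = 3))
})

test_that("stride generator hits the requested mean, CV and positivity", {
  cfg <- stride_config(n_strides = 512, hurst_target = 0.8,
                       mean_si = 1.184, cv_target = 0.026, seed = 21)
  s <- generate_fgn_strides(cfg)
  expect_equal(nrow(s), 512)
  expect_true(all(s$stride_s > 0))
  expect_equal(mean(s$stride_s), 1.184, tolerance = 0.05)
  expect_equal(coefficient_of_variation(s), 0.026, tolerance = 0.35)
  # cv_target = 0 degenerates to a constant series at the mean
  s0 <- generate_fgn_strides(stride_config(cv_target = 0, seed = 1))
  expect_true(all(s0$stride_s == 1.184))
})

test_that("stride configs implying non-positive strides are rejected", {
  expect_error(stride_config(cv_target = 0.5), "non-positive")
  expect_error(stride_config(n_strides = 10), "n_strides")
  expect_error(stride_config(hurst_target = 1.2), "hurst")
})

test_that("marker synthesis is an exact round trip without noise", {
  tr <- simulate_oscillator(osc_config(duration = 20, seed = 31))
  mk <- synthesize_markers(tr, marker_noise_sd = 0, seed = 1)
  q <- com_from_markers(mk)
  q_ref <- splinefun(tr$time_s, tr$q_m, method = "fmm")(q$time_s)
  expect_lt(max(abs(q$value - q_ref)), 1e-12)
})

test_that("marker noise averages down as 1/sqrt(4) in the recovered COM", {
  tr <- simulate_oscillator(osc_config(duration = 60, seed = 32))
  mk <- synthesize_markers(tr, marker_noise_sd = 0.5, seed = 2)
  q <- com_from_markers(mk)
  q_ref <- splinefun(tr$time_s, tr$q_m, method = "fmm")(q$time_s)
  rms_mm <- 1000 * sqrt(mean((q$value - q_ref)^2))
  expect_lt(rms_mm, 0.5 / sqrt(4) + 0.05)  # averaging bound + resampling
})

test_that("10 s at 120 Hz yields 1200 sample intervals per marker", {
  tr <- simulate_oscillator(osc_config(duration = 10, seed = 1))
  mk <- synthesize_markers(tr, rate_out = 120)
  expect_equal(nrow(mk), 1201)             # inclusive endpoints
  expect_equal(diff(range(mk$time_s)), 10, tolerance = 1e-9)
  expect_error(synthesize_markers(tr, rate_out = 0), "rate_out")
})
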