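# Cycle segmentation, per-cycle energetics, the adiabatic invariant and the
# averaged phase-space attractor.

test_that("step detection counts sine maxima and survives small noise", {
  tr <- sine_trajectory(a = 0.02, f = 2, duration = 10, rate = 1200)
  pk <- detect_steps(tr)
  expect_true(abs(length(pk) - 20) <= 1)
  # 1% amplitude white noise must not change the peak count
  set.seed(7)
  noisy <- com_trajectory(
    gait_signal(tr$q_m + 0.0002 * rnorm(nrow(tr)), rate = 1200))
  expect_equal(length(detect_steps(noisy)), length(pk))
  expect_error(detect_steps(gait_signal(rep(1, 1000), rate = 100)),
               "maxima")
})

test_that("cycles pair alternate maxima and drop a trailing step", {
  cyc <- segment_cycles(seq(1, 201, by = 10))  # 21 peaks -> 10 cycles
  expect_equal(nrow(cyc), 10)
  expect_equal(cyc$start_idx, seq(1, 181, by = 20))
  expect_equal(cyc$end_idx, seq(21, 201, by = 20))
  cyc4 <- segment_cycles(c(5, 10, 15, 20))     # 4 peaks -> 1 cycle + orphan
  expect_equal(nrow(cyc4), 1)
  expect_error(segment_cycles(c(1, 2)), "at least 3")
  # cycle count invariant: floor((n_maxima - 1) / 2)
  for (np in c(3, 6, 11, 40)) {
    expect_equal(nrow(segment_cycles(seq_len(np) * 7)), (np - 1) %/% 2)
  }
})

test_that("per-cycle mean kinetic energy matches the sine closed form", {
  # <(1/2) P^2> over one period of A sin(2 pi f t) is pi^2 f^2 A^2
  tr <- sine_trajectory(a = 1, f = 1, duration = 30, rate = 1200)
  cyc <- single_period_cycles(f = 1, rate = 1200, n_cycles = 20)
  en <- cycle_energetics(tr, cyc)
  expect_equal(en$ekbar_jkg, rep(pi^2, 20), tolerance = 1e-6)
  expect_equal(en$f_hz, rep(1, 20), tolerance = 1e-9)
  tr2 <- sine_trajectory(a = 0.02, f = 0.9, duration = 30, rate = 1200)
  en2 <- cycle_energetics(tr2, single_period_cycles(0.9, 1200, 10))
  expect_equal(mean(en2$ekbar_jkg), pi^2 * 0.9^2 * 0.02^2, tolerance = 1e-4)
  # P identically zero gives zero energy
  still <- com_trajectory(gait_signal(rep(1, 2000), rate = 100),
                          gait_signal(rep(0, 2000), rate = 100))
  expect_equal(cycle_energetics(still, single_period_cycles(1, 100, 3))$ekbar_jkg,
               rep(0, 3))
})

test_that("invariant aggregates obey their defining identities", {
  tr <- sine_trajectory(a = 1, f = 1, duration = 40, rate = 1200)
  tab <- invariant_table(tr, cycles = single_period_cycles(1, 1200, 30))
  g <- glance(tab)
  # pure sine: piI = Ekbar / f = pi^2 f A^2 with f the oscillation frequency
  expect_equal(g$pi_invariant_jskg, pi^2, tolerance = 1e-5)
  expect_equal(g$ekm_jkg, mean(tab$ekbar_jkg))
  expect_equal(g$fm_hz, mean(tab$f_hz))
  expect_equal(g$invariant_jskg, g$ekm_jkg / (pi * g$fm_hz))
  expect_equal(tab$f_hz, 1 / tab$t_s, tolerance = 1e-12)
  # all normalized pairs collapse to (1, 1) for a pure sine
  expect_equal(tab$f_rel, rep(1, 30), tolerance = 1e-9)
  expect_equal(tab$ek_rel, rep(1, 30), tolerance = 1e-6)
})

test_that("normalized pairs average to (1, 1) by construction", {
  cfg <- osc_config(omega0 = 2 * pi * 0.85, epsilon = 0.03, tau = 12,
                    duration = 120, dt = 0.005, seed = 5)
  tab <- invariant_table(simulate_oscillator(cfg))
  expect_equal(mean(tab$f_rel), 1, tolerance = 1e-12)
  expect_equal(mean(tab$ek_rel), 1, tolerance = 1e-12)
  expect_error(invariant_table(simulate_oscillator(cfg),
                               cycles = segment_cycles(c(1, 2, 3))[0, ]),
               "2 gait cycles")
})

test_that("two-step cycle pairing halves the cycle frequency of a sine", {
  # with the two-step pairing a cycle spans two oscillation periods, so a
  # 1 Hz sine yields 0.5 Hz cycles and piI twice the single-period value
  tr <- sine_trajectory(a = 1, f = 1, duration = 40, rate = 1200)
  g <- glance(invariant_table(tr))
  expect_equal(g$fm_hz, 0.5, tolerance = 1e-3)
  expect_equal(g$pi_invariant_jskg, 2 * pi^2, tolerance = 1e-2)
})

test_that("attractor of a noiseless oscillator is the exact phase ellipse", {
  # f = 0.8 Hz at 1200 Hz gives an integer 1500 samples per period, so all
  # single-period cycles are sample-identical and the bin spread is zero
  tr <- sine_trajectory(a = 0.02, f = 0.8, duration = 30, rate = 1200)
  att <- mean_attractor(tr, cycles = single_period_cycles(0.8, 1200, 10),
                        bins = 1200)
  expect_equal(nrow(att), 1200)
  expect_lt(max(att$q_sd), 1e-6)           # identical cycles: zero spread
  expect_lt(max(att$p_sd), 1e-5)
  # enclosed area = pi * A * (2 pi f A), the ellipse of semi-axes A, omega A
  area <- shoelace(att$q_mean, att$p_mean)
  expect_equal(area, pi * 0.02 * (2 * pi * 0.8 * 0.02), tolerance = 0.01)
  expect_equal(attractor_area(att), area)
  # default two-period cycles wind around the ellipse twice
  att2 <- mean_attractor(tr, bins = 1200)
  expect_equal(attractor_area(att2), 2 * pi * 0.02 * (2 * pi * 0.8 * 0.02),
               tolerance = 0.01)
})

test_that("attractor bin statistics are exact two-point statistics", {
  # two synthetic cycles with opposite Q values give mean 0 and SD |v|
  rate <- 100
  t <- seq(0, 4, by = 1 / rate)
  v <- sin(2 * pi * t)
  tr <- com_trajectory(gait_signal(c(v[1:201], -v[1:201]), rate = rate),
                       gait_signal(rep(1, 402), rate = rate))
  cyc <- tibble::tibble(cycle = 1:2, start_idx = c(1L, 202L),
                        end_idx = c(201L, 402L))
  att <- mean_attractor(tr, cycles = cyc, bins = 100)
  expect_equal(att$q_mean, rep(0, 100), tolerance = 1e-8)
  ref <- abs(spline((0:200) / 200, v[1:201], method = "fmm",
                    xout = seq(0, 1, length.out = 100))$y)
  expect_equal(att$q_sd, ref * sqrt(2), tolerance = 1e-6)
})
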