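# Statistical layer: gated paired tests, zero-intercept fits, ANCOVA, DTW.

test_that("paired comparison picks the t branch and detects a large shift", {
  withr::with_seed(21, {
    y <- rnorm(25)
    x <- y + 3 + rnorm(25)   # shift of 3 noise-SDs
    res <- paired_compare(x, y)
    expect_equal(res$test, "paired-t")
    expect_lt(res$p_value, 0.05)
    expect_equal(res$n, 25)
  })
})

test_that("paired comparison falls back to Wilcoxon for non-normal differences", {
  withr::with_seed(22, {
    y <- rnorm(30)
    x <- y + rexp(30)^3   # heavily skewed differences
    res <- paired_compare(x, y)
    expect_equal(res$test, "wilcoxon")
    expect_lt(res$shapiro_p, 0.05)
    expect_lt(res$p_value, 0.05)
  })
  expect_error(paired_compare(1:5, 1:5), "zero")
  expect_error(paired_compare(1:4, 1:5), "equal length")
})

test_that("paired comparison holds its type-I rate under a permutation null", {
  # paired permutation null: each pair's two values are randomly swapped, so
  # the differences are independent and symmetric about zero
  rej <- withr::with_seed(23, {
    vapply(1:1000, function(i) {
      a <- rnorm(20); b <- rnorm(20)
      s <- runif(20) < 0.5
      paired_compare(ifelse(s, a, b), ifelse(s, b, a))$p_value < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("zero-intercept slope equals the closed form and matches lm", {
  d <- tibble::tibble(f_rel = c(1, 2, 3), ek_rel = c(2, 4, 6))
  f <- slope_fit(d)
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)
  expect_equal(f$conf_high - f$conf_low, 0)
  f1 <- slope_fit(tibble::tibble(f_rel = c(1, 2, 5), ek_rel = c(1, 2, 5)))
  expect_equal(f1$slope, 1)
  withr::with_seed(24, {
    x <- runif(50); y <- 1.3 * x + rnorm(50, sd = 0.1)
    f2 <- slope_fit(tibble::tibble(f_rel = x, ek_rel = y))
    expect_equal(f2$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
    lmfit <- lm(y ~ x + 0)
    expect_equal(f2$slope, unname(coef(lmfit)), tolerance = 1e-12)
    expect_equal(unname(confint(lmfit)[1, ]),
                 c(f2$conf_low, f2$conf_high), tolerance = 1e-9)
  })
  expect_error(slope_fit(tibble::tibble(f_rel = c(0, 0, 0),
                                        ek_rel = c(1, 2, 3))), "zero")
  expect_error(slope_fit(tibble::tibble(f_rel = 1:2, ek_rel = 1:2)), "3 pairs")
})

test_that("tidy and glance expose the fit in broom conventions", {
  d <- tibble::tibble(f_rel = c(1, 2, 3, 4), ek_rel = c(1.1, 1.9, 3.2, 3.9))
  f <- slope_fit(d)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std_error", "conf_low",
                     "conf_high", "p_value"))
  expect_equal(td$estimate[td$term == "slope"], f$slope)
  g <- glance(f)
  expect_equal(g$n, 4)
  expect_true(is.na(g$interaction_p))
})

test_that("zero-intercept ANCOVA recovers a known slope difference", {
  withr::with_seed(28, {
    x0 <- runif(20, 0.5, 1.5)
    da0 <- tibble::tibble(f_rel = x0, ek_rel = x0 + rnorm(20, sd = 0.05))
    f0 <- ancova_zero_intercept(da0, da0)
  })
  # pooling a group with itself: interaction exactly 0, p exactly 1
  expect_equal(f0$interaction$estimate, 0, tolerance = 1e-12)
  expect_equal(f0$interaction$p_value, 1, tolerance = 1e-9)
  withr::with_seed(25, {
    xa <- runif(100, 0.5, 1.5); xb <- runif(100, 0.5, 1.5)
    da <- tibble::tibble(f_rel = xa, ek_rel = xa + rnorm(100, sd = 0.01))
    db <- tibble::tibble(f_rel = xb, ek_rel = 1.5 * xb + rnorm(100, sd = 0.01))
    f <- ancova_zero_intercept(da, db)
    # oracle: two separate zero-intercept fits
    ka <- slope_fit(da)$slope
    kb <- slope_fit(db)$slope
    expect_equal(f$slope, ka, tolerance = 1e-3)
    expect_equal(f$interaction$estimate, kb - ka, tolerance = 1e-3)
    expect_lt(f$interaction$p_value, 1e-6)
    expect_equal(glance(f)$interaction_p, f$interaction$p_value)
  })
  expect_error(
    ancova_zero_intercept(tibble::tibble(f_rel = c(0, 0, 0), ek_rel = 1:3),
                          tibble::tibble(f_rel = 1:3, ek_rel = 1:3)),
    "zero")
})

test_that("DTW distance is a z-normalized elastic distance", {
  a <- sin(seq(0, 6 * pi, length.out = 200))
  expect_equal(dtw_distance(a, a), 0)
  b <- c(tail(a, -10), head(a, 10))        # 5% circular shift
  expect_lt(dtw_distance(a, b), dtw_distance(a, rev(a)) / 3)
  expect_equal(dtw_distance(a, b), dtw_distance(b, a))    # symmetry
  expect_gte(dtw_distance(a, b), 0)
  # z-normalization makes the distance affine invariant
  expect_equal(dtw_distance(5 * a + 2, b), dtw_distance(a, b))
  expect_error(dtw_distance(rep(1, 10), a), "constant")
})

test_that("DTW matches a textbook recursive implementation on tiny inputs", {
  withr::with_seed(26, {
    for (k in 1:3) {
      a <- rnorm(12)
      b <- rnorm(15)
      expect_equal(dtw_distance(a, b), dtw_recursive(a, b), tolerance = 1e-12)
    }
  })
})

test_that("a Sakoe-Chiba band bounds the warp and errors when impossible", {
  withr::with_seed(27, {
    a <- cumsum(rnorm(100))
    b <- cumsum(rnorm(100))
    d_full <- dtw_distance(a, b)
    d_band <- dtw_distance(a, b, window = 0.1)
    expect_gte(d_band, d_full)   # constraining can only increase the cost
  })
  # attractor traces are accepted directly
  tr <- sine_trajectory(duration = 20)
  att <- mean_attractor(tr, bins = 200)
  expect_equal(dtw_distance(att, att), 0)
  expect_equal(dtw_distance(att, att, trace = "p"), 0)
})
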