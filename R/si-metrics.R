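# Stride-interval variability, predictability and complexity indices.

si_values <- function(x, what = "stride series") {
  v <- if (is.data.frame(x)) {
    if ("stride_s" %in% names(x)) x$stride_s
    else abort(sprintf("%s must be numeric or have a `stride_s` column.", what))
  } else if (is.numeric(x)) {
    as.double(x)
  } else {
    abort(sprintf("cannot interpret %s.", what))
  }
  if (anyNA(v)) abort(sprintf("%s contains missing values.", what))
  v
}

#' Coefficient of variation
#'
#' `CV = SD(T) / mean(T)` with the sample (n-1) standard deviation; the
#' standard magnitude index for stride-interval fluctuations, and an
#' empirical estimate of the fractional noise magnitude in the oscillator
#' model.
#'
#' @param x Numeric vector or a `stride_series` tibble.
#' @return A single non-negative number.
#' @examples
#' coefficient_of_variation(c(0.9, 1.1))
#' @export
coefficient_of_variation <- function(x) {
  v <- si_values(x)
  if (length(v) < 2L) abort("need at least 2 values.")
  m <- mean(v)
  if (m == 0) abort("mean is zero; CV undefined.")
  sd(v) / m
}

#' Detrended fluctuation analysis
#'
#' Computes the DFA fluctuation function: the series is mean-centered and
#' integrated into a profile; for each window size `n` (log-spaced in
#' `[win_min, win_max]`) the profile is cut into non-overlapping windows, a
#' polynomial trend of order `order` is removed per window, and `F(n)` is the
#' root-mean-square residual. The scaling exponent (Hurst exponent for
#' fGn-like series) is the least-squares slope of `log F(n)` vs `log n`.
#'
#' @param x Numeric vector or `stride_series` tibble.
#' @param win_min Smallest window size (default 16).
#' @param win_max Largest window size (default `floor(n/9)`, so at least 9
#'   windows contribute at every scale).
#' @param order Detrending polynomial order (default 1).
#' @param n_scales Number of log-spaced window sizes requested (default 10;
#'   duplicates after rounding are dropped).
#' @return A tibble of class `gait_dfa` with columns `size`, `fluctuation`
#'   and attribute `hurst` (the fitted slope). Use [hurst_dfa()] for the
#'   scalar exponent.
#' @examples
#' h <- hurst_dfa(rnorm(512))
#' @export
dfa <- function(x, win_min = 16, win_max = NULL, order = 1, n_scales = 10) {
  v <- si_values(x)
  n <- length(v)
  win_max <- win_max %||% floor(n / 9)
  if (win_max <= win_min) {
    abort(sprintf("series too short for DFA: need length >= %d (have %d).",
                  9L * as.integer(win_min) + 9L, n))
  }
  sizes <- unique(round(exp(seq(log(win_min), log(win_max),
                                length.out = n_scales))))
  sizes <- sizes[sizes > order + 1]
  profile <- cumsum(v - mean(v))
  fluct <- purrr::map_dbl(sizes, function(s) {
    nwin <- n %/% s                   # remainder at the series end is dropped
    y <- matrix(profile[seq_len(nwin * s)], nrow = s)
    qx <- qr.Q(qr(outer(seq_len(s), 0:order, "^")))
    res <- y - qx %*% crossprod(qx, y)
    sqrt(mean(res^2))
  })
  fit <- lm.fit(cbind(1, log(sizes)), log(fluct))
  out <- tibble(size = sizes, fluctuation = fluct)
  structure(out,
            class = c("gait_dfa", class(out)),
            hurst = unname(coef(fit)[2]),
            order = order)
}

#' Hurst exponent by DFA
#'
#' Scalar convenience wrapper around [dfa()].
#'
#' @inheritParams dfa
#' @return The DFA scaling exponent (Hurst exponent); 0.5 for uncorrelated
#'   series, above 0.5 persistent, below 0.5 anti-persistent.
#' @export
hurst_dfa <- function(x, win_min = 16, win_max = NULL, order = 1,
                      n_scales = 10) {
  attr(dfa(x, win_min = win_min, win_max = win_max, order = order,
           n_scales = n_scales), "hurst")
}

#' Minkowski (box-counting) fractal dimension of a series graph
#'
#' The series graph is normalized to the unit square (index and value each
#' min-max scaled to `[0, 1]`) and covered with square boxes of side
#' `delta = 2^-k`, `k = 1 .. floor(log2(n)) - 2`. `N(delta)` counts the boxes
#' intersected by the linearly interpolated graph; `D` is the slope of
#' `log N(delta)` vs `log(1/delta)`. Smooth graphs give D near 1; rougher,
#' noise-like graphs approach 2 (for fGn graphs, D is approximately 2 - H).
#'
#' @param x Numeric vector or `stride_series` tibble (length >= 64).
#' @return Estimated dimension in `[1, 2]` (clamped); a constant series
#'   returns exactly 1 with a warning.
#' @examples
#' minkowski_dimension(rnorm(256))
#' @export
minkowski_dimension <- function(x) {
  v <- si_values(x)
  n <- length(v)
  if (n < 64L) abort("need at least 64 values for the box-counting dimension.")
  rng <- range(v)
  if (diff(rng) == 0) {
    warn("constant series: graph is a line, returning D = 1")
    return(1)
  }
  tx <- (seq_len(n) - 1) / (n - 1)
  ty <- (v - rng[1]) / diff(rng)
  ks <- seq_len(floor(log2(n)) - 2L)
  counts <- purrr::map_dbl(ks, function(k) {
    m <- 2^k              # m columns of width delta = 1/m
    delta <- 1 / m
    col <- pmin(floor(tx / delta), m - 1)
    # piecewise-linear graph: within each column the extrema are attained at
    # data points inside it or at the interpolated column boundaries
    lo <- tapply(ty, col, min)
    hi <- tapply(ty, col, max)
    edges <- (1:(m - 1)) * delta
    ye <- stats::approx(tx, ty, xout = edges)$y
    for (b in seq_along(edges)) {
      for (cc in c(b - 1, b)) {       # boundary belongs to both columns
        key <- as.character(cc)
        lo[key] <- min(lo[key], ye[b], na.rm = TRUE)
        hi[key] <- max(hi[key], ye[b], na.rm = TRUE)
      }
    }
    rows <- pmin(floor(hi / delta), m - 1) - pmin(floor(lo / delta), m - 1) + 1
    sum(rows)
  })
  fit <- lm.fit(cbind(1, log(2^ks)), log(counts))
  min(max(unname(coef(fit)[2]), 1), 2)
}

#' Sample entropy
#'
#' Regularity statistic of Richman and Moorman: with template length `m` and
#' tolerance `r = r_factor * SD`, `B` counts pairs of length-`m` templates
#' within Chebyshev distance `r` (self-matches excluded), `A` the same for
#' length `m + 1`, and `S = -log(A / B)`. Larger values mean less regular,
#' more random series.
#'
#' @param x Numeric vector or `stride_series` tibble (length >= 50).
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of the series SD (default 0.2).
#' @return Sample entropy (>= 0); `Inf` with attributes `a`/`b` when no
#'   template pair extends to length `m + 1`.
#' @examples
#' sample_entropy(sin(seq_len(200) / 5) + rnorm(200, sd = 0.05))
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  v <- si_values(x)
  n <- length(v)
  if (n < 50L) abort("need at least 50 values for sample entropy.")
  s <- sd(v)
  if (s == 0) abort("constant series: sample-entropy tolerance degenerates.")
  r <- r_factor * s
  nt <- n - m                          # templates counted at both lengths
  # Chebyshev distances built up offset by offset, vectorized over pairs
  dmax <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    seg <- v[(1 + k):(nt + k)]
    dmax <- pmax(dmax, abs(outer(seg, seg, "-")))
  }
  match_m <- dmax <= r
  seg <- v[(1 + m):(nt + m)]
  match_m1 <- match_m & (abs(outer(seg, seg, "-")) <= r)
  b <- (sum(match_m) - nt) / 2         # drop self-matches, count pairs once
  a <- (sum(match_m1) - nt) / 2
  if (b == 0) abort("no template matches at length m; increase r_factor.")
  if (a == 0) {
    out <- Inf
    attr(out, "a") <- 0
    attr(out, "b") <- b
    return(out)
  }
  -log(a / b)
}

#' All stride-interval metrics at once
#'
#' Convenience wrapper computing the mean stride interval, CV
#' ([coefficient_of_variation()]), Hurst exponent ([hurst_dfa()]), Minkowski
#' dimension ([minkowski_dimension()]) and sample entropy
#' ([sample_entropy()]) of one stride-interval series.
#'
#' @param x Numeric vector or `stride_series` tibble.
#' @param ... Passed on to [hurst_dfa()].
#' @return One-row tibble with columns `n`, `si_s`, `cv`, `hurst`,
#'   `minkowski_d`, `sampen`.
#' @examples
#' strides <- generate_fgn_strides(stride_config(n_strides = 256, seed = 1))
#' si_metrics(strides)
#' @export
si_metrics <- function(x, ...) {
  v <- si_values(x)
  tibble(
    n = length(v),
    si_s = mean(v),
    cv = coefficient_of_variation(v),
    hurst = hurst_dfa(v, ...),
    minkowski_d = minkowski_dimension(v),
    sampen = as.numeric(sample_entropy(v))
  )
}
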