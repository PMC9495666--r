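# Independent oracles used across the suite. These deliberately use naive
# O(n^2)/O(n^3) formulations so they share no code path with the package.

# Sample entropy by explicit template-pair enumeration.
sampen_bruteforce <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * sd(x)
  count_matches <- function(len) {
    nt <- n - m                       # same template count at both lengths
    cnt <- 0L
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r) {
          cnt <- cnt + 1L
        }
      }
    }
    cnt
  }
  b <- count_matches(m)
  a <- count_matches(m + 1)
  -log(a / b)
}

# Exact-covariance fGn by Cholesky factorization of the full Toeplitz
# covariance matrix (feasible for small n only).
fgn_cholesky <- function(n, hurst, seed) {
  k <- 0:(n - 1)
  gam <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
  sig <- stats::toeplitz(gam)
  l <- chol(sig)
  withr::with_seed(seed, as.vector(t(l) %*% rnorm(n)))
}

# Autocovariance of fGn at lag k (unit variance).
fgn_acov <- function(k, hurst) {
  0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
           abs(k - 1)^(2 * hurst))
}

# Textbook recursive DTW on z-normalized series (tiny inputs only).
dtw_recursive <- function(a, b) {
  a <- (a - mean(a)) / sd(a)
  b <- (b - mean(b)) / sd(b)
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- abs(a[i] - b[j]) + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# Shoelace polygon area.
shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Analytic trajectory of the noise-free oscillator sampled like the
# simulator output.
sine_trajectory <- function(a = 0.02, f = 0.9, duration = 30, rate = 1200) {
  t <- seq(0, duration, by = 1 / rate)
  com_trajectory(
    gait_signal(a * sin(2 * pi * f * t), rate = rate),
    gait_signal(2 * pi * f * a * cos(2 * pi * f * t), rate = rate)
  )
}

# Cycle boundaries spanning exactly one oscillation period each, anchored at
# the sine maxima (phase pi/2): used to test the aggregation closed forms
# independently of the two-step pairing policy.
single_period_cycles <- function(f, rate, n_cycles, t0 = 1 / (4 * f)) {
  starts <- round((t0 + (seq_len(n_cycles) - 1) / f) * rate) + 1L
  tibble::tibble(cycle = seq_len(n_cycles),
                 start_idx = starts,
                 end_idx = round((t0 + seq_len(n_cycles) / f) * rate) + 1L)
}
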