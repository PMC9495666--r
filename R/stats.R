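# Statistical layer: normality-gated paired comparisons, zero-intercept
# slope fits and ANCOVA, and dynamic time warping distances.

#' Normality-gated paired comparison
#'
#' Tests a within-subject difference between two conditions. The differences
#' `x - y` are first checked for normality (Shapiro-Wilk); if the check
#' passes at level `alpha` a paired t-test is used, otherwise a Wilcoxon
#' signed-rank test (zero differences dropped; exact p-value for n <= 25,
#' normal approximation with continuity/tie correction above).
#'
#' @param x,y Numeric vectors of equal length (>= 3), paired by position.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @return One-row tibble with `test` ("paired-t" or "wilcoxon"),
#'   `statistic`, `p_value`, `shapiro_p`, `n`.
#' @examples
#' paired_compare(rnorm(20, 1), rnorm(20))
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("need at least 3 pairs.")
  d <- x - y
  if (all(d == 0)) abort("all paired differences are zero; comparison is degenerate.")
  sw <- shapiro.test(d)
  if (sw$p.value >= alpha) {
    ht <- t.test(x, y, paired = TRUE)
    test <- "paired-t"
  } else {
    d_nz <- d[d != 0]
    exact <- length(d_nz) <= 25 && !any(duplicated(abs(d_nz)))
    ht <- suppressWarnings(
      wilcox.test(d_nz, exact = exact, correct = TRUE))
    test <- "wilcoxon"
  }
  tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    shapiro_p = sw$p.value,
    n = length(x)
  )
}

new_slope_fit <- function(slope, se, ci, r2, n, df,
                          interaction = NULL) {
  structure(
    list(slope = slope, se = se, conf_low = ci[1], conf_high = ci[2],
         r_squared = r2, n = n, df = df, interaction = interaction),
    class = "slope_fit")
}

#' Zero-intercept linear regression of the normalized energy-frequency law
#'
#' Least-squares fit through the origin, `y = k x`, with
#' `k = sum(xy) / sum(x^2)`, a t-based 95% confidence interval on `k`
#' (`n - 1` residual degrees of freedom), and `R^2` measured against the
#' zero-intercept null (`1 - RSS / sum(y^2)`). Applied to the normalized
#' pairs `(f_i/fm, Ekbar_i/Ekm)` of a gait-cycle table this tests the
#' adiabatic-invariance prediction `k = 1`.
#'
#' @param data A data frame of pairs — by default a `gait_cycle_table` with
#'   columns `f_rel`, `ek_rel`.
#' @param x,y Column names (unquoted) of the predictor and response.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return A `slope_fit` object; see [tidy.slope_fit()] and
#'   [glance.slope_fit()].
#' @examples
#' traj <- simulate_oscillator(osc_config(duration = 60, seed = 1))
#' fit <- slope_fit(invariant_table(traj))
#' tidy(fit)
#' @export
slope_fit <- function(data, x = f_rel, y = ek_rel, conf_level = 0.95) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n < 3L) abort("need at least 3 pairs.")
  sxx <- sum(xv^2)
  if (sxx == 0) abort("all predictor values are zero; slope undefined.")
  k <- sum(xv * yv) / sxx
  rss <- sum((yv - k * xv)^2)
  df <- n - 1L
  se <- sqrt(rss / df / sxx)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  r2 <- 1 - rss / sum(yv^2)
  new_slope_fit(k, se, k + c(-1, 1) * tcrit * se, r2, n, df)
}

#' Zero-intercept ANCOVA comparing slopes between two conditions
#'
#' Fits `y = k x + k_delta (x * 1[group B])` with no intercept on the pooled
#' pairs of two groups and reports the reference slope `k`, the
#' slope-difference (interaction) estimate `k_delta` and its t-test p-value.
#' A non-significant interaction means the energy-frequency trend does not
#' depend on the condition.
#'
#' @param data_a,data_b Pair tables for the two conditions (see
#'   [slope_fit()]).
#' @param x,y Column names (unquoted) of the predictor and response.
#' @param conf_level Confidence level for the reference-slope interval.
#' @return A `slope_fit` whose `interaction` field is a list with
#'   `estimate`, `se`, `statistic`, `p_value`.
#' @examples
#' t1 <- simulate_oscillator(osc_config(duration = 60, seed = 1))
#' t2 <- simulate_oscillator(osc_config(duration = 60, seed = 2))
#' fit <- ancova_zero_intercept(invariant_table(t1), invariant_table(t2))
#' glance(fit)
#' @export
ancova_zero_intercept <- function(data_a, data_b, x = f_rel, y = ek_rel,
                                  conf_level = 0.95) {
  xa <- dplyr::pull(data_a, {{ x }}); ya <- dplyr::pull(data_a, {{ y }})
  xb <- dplyr::pull(data_b, {{ x }}); yb <- dplyr::pull(data_b, {{ y }})
  if (length(xa) < 3L || length(xb) < 3L) abort("each group needs at least 3 pairs.")
  if (sum(xa^2) == 0 || sum(xb^2) == 0) {
    abort("a group has all-zero predictor values; slope undefined.")
  }
  xv <- c(xa, xb)
  yv <- c(ya, yb)
  grp_b <- rep(c(0, 1), c(length(xa), length(xb)))
  fit <- lm(yv ~ 0 + xv + xv:grp_b)
  sm <- summary(fit)$coefficients
  k <- sm["xv", "Estimate"]
  se <- sm["xv", "Std. Error"]
  df <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  r2 <- 1 - sum(fit$residuals^2) / sum(yv^2)
  inter <- list(
    estimate = sm["xv:grp_b", "Estimate"],
    se = sm["xv:grp_b", "Std. Error"],
    statistic = sm["xv:grp_b", "t value"],
    p_value = sm["xv:grp_b", "Pr(>|t|)"]
  )
  new_slope_fit(k, se, k + c(-1, 1) * tcrit * se, r2, length(xv), df,
                interaction = inter)
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Zero-intercept fit: k = %.4f [%.4f, %.4f], R^2 = %.4f, n = %d\n",
              x$slope, x$conf_low, x$conf_high, x$r_squared, x$n))
  if (!is.null(x$interaction)) {
    cat(sprintf("  slope x condition interaction: %.4f (p = %.3g)\n",
                x$interaction$estimate, x$interaction$p_value))
  }
  invisible(x)
}

#' Tidy a zero-intercept fit
#' @param x A `slope_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term (`slope`, and
#'   `slope_interaction` for ANCOVA fits).
#' @export
tidy.slope_fit <- function(x, ...) {
  out <- tibble(
    term = "slope",
    estimate = x$slope,
    std_error = x$se,
    conf_low = x$conf_low,
    conf_high = x$conf_high,
    p_value = NA_real_
  )
  if (!is.null(x$interaction)) {
    out <- dplyr::bind_rows(out, tibble(
      term = "slope_interaction",
      estimate = x$interaction$estimate,
      std_error = x$interaction$se,
      conf_low = NA_real_,
      conf_high = NA_real_,
      p_value = x$interaction$p_value
    ))
  }
  out
}

#' One-row summary of a zero-intercept fit
#' @param x A `slope_fit`.
#' @param ... Unused.
#' @return Tibble with `slope`, `conf_low`, `conf_high`, `r_squared`, `n`,
#'   and the interaction p-value (NA for plain fits).
#' @export
glance.slope_fit <- function(x, ...) {
  tibble(
    slope = x$slope,
    conf_low = x$conf_low,
    conf_high = x$conf_high,
    r_squared = x$r_squared,
    n = x$n,
    interaction_p = if (is.null(x$interaction)) NA_real_ else x$interaction$p_value
  )
}

#' Dynamic time warping distance between z-normalized series
#'
#' Classic DTW with the symmetric step pattern and absolute-difference local
#' cost. Both inputs are z-normalized first (so the distance is invariant to
#' affine transforms of either series); an optional Sakoe-Chiba band caps
#' the warping for long inputs. Intended for comparing COM position or
#' velocity traces (e.g. the 1200-point mean attractor traces of two
#' conditions).
#'
#' @param a,b Numeric vectors, `gait_signal`s, or `gait_attractor`s (for
#'   attractors, the trace picked by `trace`).
#' @param trace For attractor inputs: `"q"` (position, default) or `"p"`
#'   (velocity).
#' @param window Sakoe-Chiba half-width as a fraction of the series length
#'   (e.g. 0.1), or NULL (default) for unconstrained warping.
#' @param normalize Z-normalize inputs first (default TRUE, recommended).
#' @return The cumulative alignment distance (>= 0).
#' @examples
#' a <- sin(seq(0, 6 * pi, length.out = 200))
#' dtw_distance(a, a) # 0
#' @export
dtw_distance <- function(a, b, trace = c("q", "p"), window = NULL,
                         normalize = TRUE) {
  trace <- match.arg(trace)
  pick <- function(x) {
    if (inherits(x, "gait_attractor")) {
      if (trace == "q") x$q_mean else x$p_mean
    } else {
      signal_values(x)
    }
  }
  av <- pick(a)
  bv <- pick(b)
  if (normalize) {
    if (sd(av) == 0 || sd(bv) == 0) {
      abort("constant input: z-normalization undefined.")
    }
    av <- (av - mean(av)) / sd(av)
    bv <- (bv - mean(bv)) / sd(bv)
  }
  win <- if (is.null(window)) -1L else as.integer(ceiling(window * max(length(av), length(bv))))
  d <- .dtw_cost(av, bv, win)
  if (!is.finite(d)) abort("Sakoe-Chiba band too narrow for these lengths.")
  d
}
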