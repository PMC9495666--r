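---
title: "Adiabatic invariance of COM motion and stride-interval structure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adiabatic invariance of COM motion and stride-interval structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiagait)
```

## The model and its assumptions

Steady walking is quasi-periodic: the vertical center-of-mass (COM)
position `Q(t)` oscillates once per step, while stride timing fluctuates
from cycle to cycle. `adiagait` models `Q(t)` as a harmonic oscillator with
a stochastically modulated frequency,

$$\ddot Q = -\omega(t)^2\,Q, \qquad \omega(t) = \omega_0\,(1 + \varepsilon\,\xi(t)),$$

with $0 \le \varepsilon \ll 1$ and $\xi(t)$ unit-variance noise. The
momentum is $P = \dot Q$, and all energies are per unit mass (J/kg; the
mass scale is fixed to 1). When $\omega$ changes slowly compared to the
oscillation, the action $E/\omega$ — equivalently the per-cycle quantity
$\bar E_{k,i}/(\pi f_i)$, with $\bar E_{k,i}$ the cycle's mean kinetic
energy and $f_i$ its frequency — is an *adiabatic invariant*: it stays
approximately constant even though $\bar E_{k,i}$ and $f_i$ both drift.
Averaging over cycles ($E_{km}$, $f_m$) defines the invariant
$I = E_{km}/(\pi f_m)$, and eliminating $I$ yields the testable
prediction

$$\frac{\bar E_{k,i}}{E_{km}} = \frac{f_i}{f_m},$$

a line of slope 1 through the origin in normalized coordinates. The
package reports $\pi I$ alongside $I$ because the invariant is usually
quoted in that form (healthy adults walk at $\pi I \sim 0.014$ J·s/kg).

Assumptions worth stating explicitly: (i) vertical motion only — the
anteroposterior and mediolateral directions have their own dynamics
(station-keeping on a treadmill, foot placement) and are excluded; (ii)
the noise is *fractional and slow* ($\varepsilon \ll 1$, correlation time
$\tau$ of several periods), which is also why the stride-interval
coefficient of variation — empirically a few percent — doubles as an
estimate of $\varepsilon$; (iii) a single degree of freedom, so the model
says nothing about inter-segmental coordination.

### Noise realization

The noise law of $\xi(t)$ is a modelling choice, not something the theory
fixes. The default is an Ornstein–Uhlenbeck (OU) process with correlation
time `tau` (default 12 s, i.e. ~10 cycles), sampled with its exact
discretization, which makes "slow external change" an explicit, tunable
property. A `"percycle"` mode (one i.i.d. draw per oscillation period,
held constant) is available as the style of per-step parameter update used
in inverted-pendulum gait models.

One subtlety the OU choice exposes: an OU process is slow *on average*
but its spectrum has a tail at all frequencies, including $2\omega$, where
frequency modulation pumps the oscillator parametrically. The per-cycle
invariant therefore does not merely jitter by $O(\varepsilon)$: over long
horizons it performs a slow random walk, with relative spread growing
roughly like $\varepsilon\sqrt{t/\tau}$ (e.g. ~10–30% after 500 cycles at
$\varepsilon = 0.03$, $\tau = 12$ s). This is genuine dynamics, not
integrator error. The test suite pins down both regimes: in the slow/short
regime ($\tau = 40$ s, ~125 cycles) the spread stays below 5% at
$\varepsilon = 0.03$, and the spread is monotone in
$\varepsilon \in \{0.01, 0.03, 0.05\}$. Crucially, the slope-1 law is
insensitive to this diffusion — each cycle still satisfies
$\bar E_k = \pi I f$ for its *current* action — which is exactly why the
regression slope is the robust group-level statistic.

### Integrator

Fixed-step classical RK4 on $(Q, P)$, with the noise generated on the
half-step grid so stage evaluations see the exact mid-step frequency; a
symplectic leapfrog is available via `integrator = "leapfrog"`. RK4 is not
symplectic, so a conservation gate protects against drift: at
$\varepsilon = 0$ and the default `dt = 0.005` s the total energy is
conserved to better than $10^{-6}$ (relative) over 100 cycles; leapfrog
shows bounded $O((\omega\,\mathrm{d}t)^2)$ energy oscillation but no
secular drift. `osc_config()` refuses steps coarser than 20 per period.

### Default study conditions

`osc_config()` defaults emulate comfortable treadmill walking:
$\omega_0 = 2\pi \cdot 1.7$ rad/s (the COM bobs once per ~0.59 s step, two
steps per ~1.18 s gait cycle), half-range `amplitude0 = 0.02` m (~4 cm
peak-to-peak COM excursion), $\varepsilon = 0.026$ (the observed CV
scale), $\tau = 12$ s, 600 s duration. These reproduce ~505 cycles per
10-minute walk, mean stride interval ~1.18 s and $\pi I \approx 0.0137$
J·s/kg — the magnitudes seen in healthy young adults. For a pure
oscillation these defaults give the closed form
$\pi I = 2\pi^2 f_Q A^2 \approx 0.0136$ J·s/kg (see below for the
factor 2).

`stride_config()` defaults (512 strides, Hurst 0.85, mean 1.184 s, CV
0.026) match the persistent fractal structure of self-paced adult walking;
Hurst 0.5 models the near-random structure seen under metronome pacing.

## From markers to cycles

`process_markers()` chains the kinematic pre-processing:

1. **COM estimate** — per-sample arithmetic mean of the four pelvic
   markers (RASI, LASI, RPSI, LPSI), mm → m. Constant marker offsets
   cancel provided they sum to zero.
2. **Adaptive low-pass** — a fourth-order Butterworth applied
   forward-backward (zero phase, so step timing is unbiased), with the
   cutoff adjusted per series so that the *filtered output* retains
   99.99% of the mean-removed power. Selecting instead the frequency where
   the cumulative periodogram reaches 99.99% and placing the −3 dB point
   there would clip a spectral line at the band edge by ~40%; the
   retained-power criterion (solved by bisection, the cumulative quantile
   serving as a lower bracket) is the reading that actually preserves the
   stated power fraction. If no admissible cutoff exists below Nyquist
   (e.g. a flat spectrum) the signal is returned unchanged with a warning.
3. **×10 cubic-spline upsampling** — 120 Hz capture to 1200 Hz. Splines
   use Forsythe ("fmm") end conditions, which reproduce cubic polynomials
   exactly; a natural spline would force zero curvature at the ends and
   distort the first/last fraction of a second.
4. **Finite differences** — central differences in the interior, one-sided
   at the edges, giving `P = dQ/dt` at 1200 Hz.

**Cycle segmentation.** A step is the span between two successive maxima
of `Q(t)`; a gait cycle is two consecutive steps, i.e. maxima
(1→3), (3→5), …, a trailing unpaired step being dropped. Peak detection
keeps maxima with topographic prominence at least 10% of the
interquartile range of `Q` and enforces a minimum separation of half the
median inter-peak interval of an unconstrained first pass (both
configurable); these thresholds are deliberately permissive because the
signal reaching them is already low-passed. The pairing is anchored at the
first detected maximum and is foot-agnostic — stride series measured from
force-plate heel strikes are a separate input, not derived from the
kinematics.

A consequence of the two-step pairing worth keeping in mind when writing
closed-form checks: for a *pure sine* at frequency $f_Q$ the detected
cycle spans two oscillation periods, so the cycle frequency is $f_Q/2$ and
$\pi I = \bar E_k/f = 2\pi^2 f_Q A^2$ — twice the single-period value
$\pi^2 f_Q A^2$. The test suite asserts the single-period closed forms by
passing explicit one-period cycle boundaries, and the pipeline-level value
with the factor 2.

**Energetics.** $\bar E_{k,i}$ is the arithmetic mean of $P^2/2$ over the
cycle's samples (half-open span, so shared boundary samples are not
double-counted). At 1200 Hz the difference from trapezoidal quadrature is
negligible (~$10^{-6}$ relative); the arithmetic mean is used.

**Attractor.** Each cycle is normalized to unit duration, `Q` and `P` are
spline-resampled at 1200 equally spaced points, and bin-wise means and
standard deviations are taken across cycles (sample SD, $n-1$
denominator). The mean loop is the phase-space attractor; for the
noise-free oscillator its enclosed (shoelace) area is the ellipse area
$\pi A \cdot \omega A$ per winding — and, because a two-step cycle winds
the ellipse twice, `attractor_area()` on default cycles returns twice
that. Real gait breaks the two steps' symmetry, so empirical attractors
are genuine double loops.

## Stride-interval estimators

**CV** — sample SD over mean.

**DFA Hurst exponent** — profile (cumulative sum of the mean-centered
series), non-overlapping windows of log-spaced sizes in
$[16, \lfloor n/9\rfloor]$ (about 10 sizes), order-1 polynomial detrending
per window, $F(n)$ the RMS residual, and $H$ the least-squares slope of
$\log F$ vs $\log n$. The window range and detrending order follow the
standard guidelines for stride-interval series; both are arguments. The
remainder at the series end is dropped and no reversed pass is averaged
in — the simplest defensible reading — which is why the estimate is
stable but not bit-identical under time reversal. Calibration (asserted in
the tests): mean estimate $0.50 \pm 0.05$ on white noise and within
$[0.7, 0.9]$ for fGn generated at $H = 0.8$ ($n = 512$, 50 replicates).

**Minkowski (box-counting) dimension** — the series graph is min–max
normalized to the unit square, covered with boxes of side $2^{-k}$,
$k = 1, \dots, \lfloor\log_2 n\rfloor - 2$, counting boxes crossed by the
linearly interpolated graph; $D$ is the slope of $\log N(\delta)$ vs
$\log(1/\delta)$. This convention is fixed here because the literature on
stride-interval fractal dimension uses graph box-counting without a single
canonical normalization. A caution documented deliberately: the textbook
duality $D = 2 - H$ describes the graph of a *continuous* fractional
Brownian profile in the fine-scale limit. For an i.i.d.-sampled series
graph at the scales available from $n \sim 10^3$ points (boxes no smaller
than 4 samples), per-column variation barely shrinks with $\delta$ and the
estimator sits well above $2 - H$ (white noise measures $D \approx 1.78$,
not 1.5). Published stride-interval values ($D \approx 1.6$–1.7 for
series with $H \approx 0.4$–0.85) are consistent with this estimator
class, not with $2 - H$. The tests therefore assert the properties that do
hold: smooth graphs give $D \approx 1$, affine value changes leave $D$
unchanged, $D \in [1, 2]$, and rougher series measure larger $D$.

**Sample entropy** — Richman–Moorman convention: template length `m = 2`,
tolerance `r = 0.2·SD`, Chebyshev distance, self-matches excluded, the
same $n - m$ templates counted at both lengths, $S = -\log(A/B)$. The
vectorized implementation is verified against brute-force pair enumeration
(exact equality for $n \le 200$). Degenerate cases: constant series are an
error (the tolerance collapses); if no template extends ($A = 0$), `Inf`
is returned with the counts attached.

## Statistical layer

Paired condition effects use a Shapiro–Wilk gate at $\alpha = 0.05$ on the
differences: normal → paired *t*; otherwise Wilcoxon signed rank (zero
differences dropped, exact p for $n \le 25$ without ties, normal
approximation with continuity correction above). The type-I rate is
checked under the paired permutation null — each pair's two values swapped
at random, so differences are independent and symmetric; permuting one
whole vector against the other is *not* a valid null here, since it forces
the differences to sum to zero exactly.

The slope-1 law is tested with least squares through the origin
($k = \sum xy/\sum x^2$, *t*-based CI on $n-1$ df, $R^2$ against the
zero-intercept null) and a zero-intercept ANCOVA
$y = kx + k_\Delta\,(x\cdot\mathbb 1[\text{group B}])$ whose interaction
term asks whether the slope depends on condition.

Dynamic time warping (symmetric step, absolute-difference local cost,
z-normalized inputs, optional Sakoe–Chiba band) compares COM traces
between conditions. The default inputs are the two 1200-point mean
attractor traces rather than full 10-minute series: DTW is $O(N^2)$, the
attractor is the natural condition-level summary, and z-normalized
distances at this length have the $O(10)$ magnitude familiar from gait
comparisons. Full-series use is possible explicitly with a band.

## What the generator does and does not emulate

Synthetic marker files reproduce: the quasi-sinusoidal COM signal with
slowly wandering frequency, four markers with zero-sum constant vertical
offsets, i.i.d. Gaussian measurement noise (default 0.5 mm), 120 Hz
sampling. Synthetic stride series reproduce the mean, CV and Hurst
exponent of real SI data with exact-covariance fGn (Davies–Harte circulant
embedding; negative circulant eigenvalues — which do not occur for fGn at
these lengths — would be truncated with renormalization and a message).

Not emulated: step-to-step left/right asymmetry (real `Q(t)` has unequal
double bumps), slow postural drift on the treadmill, marker occlusions and
gap-filling artefacts, coloured measurement noise, and any coupling
between the COM trace and the stride series (they are generated
independently, whereas in a walker the same rhythm drives both). Passing
tests therefore demonstrate that the estimators and the pipeline recover
known ground truth under the model's assumptions — not that the model
captures every feature of laboratory data.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to run in
seconds while keeping estimator variance low: 500-cycle runs for the
slope law, 50 replicates of $n = 512$ for DFA calibration, 20 replicate
pairs of ~60-cycle runs for the ANCOVA null, 1000 replicates for the
type-I rate, 3 seeds per $\varepsilon$ for the drift monotonicity. All
randomness flows through explicit integer seeds; identical configuration
plus seed yields byte-identical output files, which the tests assert.

## Known limitations

- The estimator of `I` inherits the cycle-segmentation policy; pathological
  gait with extra COM maxima per step would need retuned peak-detection
  thresholds.
- DFA on short series ($n \lesssim 256$) uses a narrow scale range
  ($[16, n/9]$) and is accordingly noisy; compare cohorts, not
  individuals.
- The box-counting dimension is scale-limited (see above) and best read as
  a relative roughness index within a fixed $n$.
- Long simulations at $\varepsilon > 0$ show genuine action diffusion;
  `I` estimated from different non-overlapping segments of one long run
  will differ more than naive per-cycle scatter suggests.
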