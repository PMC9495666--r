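#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step integrators for the frequency-modulated oscillator
//   Qdot = P,  Pdot = -omega(t)^2 Q
// omega_half holds omega on the half-step grid t = 0, dt/2, dt, ... so the
// RK4 stages see the exact mid-step frequency (2*nstep + 1 values).

// [[Rcpp::export(name = ".integrate_rk4")]]
NumericMatrix integrate_rk4(NumericVector omega_half, double q0, double p0,
                            double dt) {
  int nstep = (omega_half.size() - 1) / 2;
  NumericMatrix out(nstep + 1, 2);
  double q = q0, p = p0;
  out(0, 0) = q;
  out(0, 1) = p;
  for (int k = 0; k < nstep; ++k) {
    double w0 = omega_half[2 * k];
    double wm = omega_half[2 * k + 1];
    double w1 = omega_half[2 * k + 2];
    double w0sq = w0 * w0, wmsq = wm * wm, w1sq = w1 * w1;

    double k1q = p, k1p = -w0sq * q;
    double k2q = p + 0.5 * dt * k1p, k2p = -wmsq * (q + 0.5 * dt * k1q);
    double k3q = p + 0.5 * dt * k2p, k3p = -wmsq * (q + 0.5 * dt * k2q);
    double k4q = p + dt * k3p, k4p = -w1sq * (q + dt * k3q);

    q += dt / 6.0 * (k1q + 2.0 * k2q + 2.0 * k3q + k4q);
    p += dt / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
    out(k + 1, 0) = q;
    out(k + 1, 1) = p;
  }
  return out;
}

// [[Rcpp::export(name = ".integrate_leapfrog")]]
NumericMatrix integrate_leapfrog(NumericVector omega_half, double q0,
                                 double p0, double dt) {
  int nstep = (omega_half.size() - 1) / 2;
  NumericMatrix out(nstep + 1, 2);
  double q = q0, p = p0;
  out(0, 0) = q;
  out(0, 1) = p;
  for (int k = 0; k < nstep; ++k) {
    double w0 = omega_half[2 * k];
    double w1 = omega_half[2 * k + 2];
    double ph = p - 0.5 * dt * w0 * w0 * q;
    q += dt * ph;
    p = ph - 0.5 * dt * w1 * w1 * q;
    out(k + 1, 0) = q;
    out(k + 1, 1) = p;
  }
  return out;
}

// Classic dynamic time warping cumulative cost, symmetric step pattern
// D[i,j] = |a_i - b_j| + min(D[i-1,j], D[i,j-1], D[i-1,j-1]),
// optional Sakoe-Chiba band of half-width `window` samples (<0 = none).

// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector a, NumericVector b, int window) {
  int n = a.size(), m = b.size();
  const double inf = R_PosInf;
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 1, jhi = m;
    if (window >= 0) {
      // band centred on the diagonal scaled to unequal lengths
      double c = (double)i * m / n;
      jlo = std::max(1, (int)std::ceil(c - window));
      jhi = std::min(m, (int)std::floor(c + window));
      if (jlo > jhi) { prev.swap(cur); continue; }
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = std::abs(a[i - 1] - b[j - 1]);
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = d + best;
    }
    prev.swap(cur);
  }
  return prev[m];
}
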