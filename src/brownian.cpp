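#include <Rcpp.h>
using namespace Rcpp;

// Reflected 2-D Brownian motion inside a disc of given radius centred at the
// origin. Each molecule i starts at (x0[i], y0[i]) and takes n_steps Gaussian
// steps with per-axis variance 2*D[i]*dt. Steps leaving the disc are folded
// radially (|r| -> 2R - |r|), the standard specular-reflection approximation
// for step sizes small relative to R. radius = R_PosInf disables confinement.
// Draws come from R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_reflected_bm(NumericVector x0, NumericVector y0, NumericVector D,
                      int n_steps, double dt, double radius) {
  int n = x0.size();
  if (y0.size() != n || D.size() != n)
    stop("x0, y0, D must have equal length");
  NumericMatrix X(n, n_steps + 1), Y(n, n_steps + 1);
  bool confined = R_finite(radius);
  for (int i = 0; i < n; ++i) { X(i, 0) = x0[i]; Y(i, 0) = y0[i]; }
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(2.0 * D[i] * dt);
      double x = X(i, s - 1) + (sd > 0 ? R::rnorm(0.0, sd) : 0.0);
      double y = Y(i, s - 1) + (sd > 0 ? R::rnorm(0.0, sd) : 0.0);
      if (confined) {
        double r = std::sqrt(x * x + y * y);
        int guard = 0;
        while (r > radius && guard++ < 64) {
          double rnew = 2.0 * radius - r;
          if (rnew < 0) rnew = radius; // pathological step > 2R: clamp to wall
          x *= rnew / r; y *= rnew / r;
          r = std::sqrt(x * x + y * y);
        }
      }
      X(i, s) = x; Y(i, s) = y;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y);
}

// Time-averaged MSD for many trajectories stored contiguously. start is
// 0-based offset of each trajectory in x/y, len its number of points.
// Returns msd (n_traj x n_lags) and the number of displacement pairs per lag.
// [[Rcpp::export]]
List cpp_msd_grouped(NumericVector x, NumericVector y, IntegerVector start,
                     IntegerVector len, int n_lags) {
  int nt = start.size();
  NumericMatrix msd(nt, n_lags);
  IntegerMatrix cnt(nt, n_lags);
  for (int t = 0; t < nt; ++t) {
    int s0 = start[t], L = len[t];
    for (int lag = 1; lag <= n_lags; ++lag) {
      int np = L - lag;
      double acc = 0.0;
      for (int j = 0; j < np; ++j) {
        double dx = x[s0 + j + lag] - x[s0 + j];
        double dy = y[s0 + j + lag] - y[s0 + j];
        acc += dx * dx + dy * dy;
      }
      msd(t, lag - 1) = np > 0 ? acc / np : NA_REAL;
      cnt(t, lag - 1) = np > 0 ? np : 0;
    }
  }
  return List::create(_["msd"] = msd, _["n_pairs"] = cnt);
}
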