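// Inner loop of multivariate EMD: directional projections, extrema with
// plateau midpoints, mirror-extended natural cubic spline envelopes, and the
// direction-averaged local mean + envelope amplitude.
//
// The tridiagonal natural-spline system depends only on the knot locations,
// so it is factored once per projection and reused for every channel; the
// spline is then evaluated for all channels in a single march over the
// sample grid.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// extrema of p with plateau midpoints; returns 0-based sample indices
static void find_extrema_cpp(const std::vector<double>& p,
                             std::vector<int>& maxima,
                             std::vector<int>& minima) {
  const int n = (int)p.size();
  std::vector<int> nz, sv;
  nz.reserve(n);
  sv.reserve(n);
  for (int i = 0; i + 1 < n; ++i) {
    double d = p[i + 1] - p[i];
    int s = (d > 0) - (d < 0);
    if (s != 0) {
      nz.push_back(i);
      sv.push_back(s);
    }
  }
  maxima.clear();
  minima.clear();
  for (size_t j = 0; j + 1 < nz.size(); ++j) {
    if (sv[j] > 0 && sv[j + 1] < 0)
      maxima.push_back((nz[j] + nz[j + 1] + 1) / 2);
    else if (sv[j] < 0 && sv[j + 1] > 0)
      minima.push_back((nz[j] + nz[j + 1] + 1) / 2);
  }
}

// mirror two extrema about each end; idx 0-based, times 1-based; returns
// knot times and the extremum row feeding each knot, deduplicated
static void mirror_knots(const std::vector<int>& idx, int n,
                         std::vector<double>& knots, std::vector<int>& rows) {
  const int m = (int)idx.size();
  knots.clear();
  rows.clear();
  double t0 = idx[0] + 1.0, t1 = idx[1] + 1.0;
  double tl = idx[m - 1] + 1.0, tl2 = idx[m - 2] + 1.0;
  double lt[2] = {2.0 - t1, 2.0 - t0};
  int lr[2] = {1, 0};
  for (int j = 0; j < 2; ++j) {
    if (knots.empty() || lt[j] > knots.back()) {
      knots.push_back(lt[j]);
      rows.push_back(lr[j]);
    }
  }
  for (int j = 0; j < m; ++j) {
    double tt = idx[j] + 1.0;
    if (tt > knots.back()) {
      knots.push_back(tt);
      rows.push_back(j);
    }
  }
  double rt[2] = {2.0 * n - tl, 2.0 * n - tl2};
  int rr[2] = {m - 1, m - 2};
  for (int j = 0; j < 2; ++j) {
    if (rt[j] > knots.back()) {
      knots.push_back(rt[j]);
      rows.push_back(rr[j]);
    }
  }
}

// workspace shared across directions to avoid reallocation
struct EnvWork {
  std::vector<double> proj, knots, yk, hseg, wfac, bfac, rhs, M, env;
  std::vector<int> maxima, minima, rows;
};

// natural cubic spline through the knot set for all channels at once,
// written into env (n x nc, column major)
static void spline_envelope(const std::vector<double>& x,
                            const std::vector<int>& idx,
                            const std::vector<int>& rows,
                            const double* V, int n, int nc,
                            EnvWork& w, std::vector<double>& env) {
  const int m = (int)x.size();
  // gather knot values: yk is m x nc
  w.yk.resize((size_t)m * nc);
  for (int c = 0; c < nc; ++c) {
    const double* col = V + (size_t)c * n;
    double* yc = w.yk.data() + (size_t)c * m;
    for (int j = 0; j < m; ++j) yc[j] = col[idx[rows[j]]];
  }
  // factor the tridiagonal system (knot-only): unknowns i = 1..m-2
  w.hseg.resize(m - 1);
  for (int i = 0; i + 1 < m; ++i) w.hseg[i] = x[i + 1] - x[i];
  w.M.assign((size_t)m * nc, 0.0);
  if (m > 2) {
    const int k = m - 2;
    w.bfac.resize(k);
    w.wfac.resize(k);
    w.bfac[0] = 2.0 * (w.hseg[0] + w.hseg[1]);
    w.wfac[0] = 0.0;
    for (int i = 1; i < k; ++i) {
      w.wfac[i] = w.hseg[i] / w.bfac[i - 1];
      w.bfac[i] = 2.0 * (w.hseg[i] + w.hseg[i + 1]) - w.wfac[i] * w.hseg[i];
    }
    w.rhs.resize(k);
    for (int c = 0; c < nc; ++c) {
      const double* yc = w.yk.data() + (size_t)c * m;
      double* Mc = w.M.data() + (size_t)c * m;
      for (int i = 1; i <= k; ++i) {
        w.rhs[i - 1] = 6.0 * ((yc[i + 1] - yc[i]) / w.hseg[i] -
                              (yc[i] - yc[i - 1]) / w.hseg[i - 1]);
      }
      for (int i = 1; i < k; ++i) w.rhs[i] -= w.wfac[i] * w.rhs[i - 1];
      Mc[k] = w.rhs[k - 1] / w.bfac[k - 1];
      for (int i = k - 1; i >= 1; --i)
        Mc[i] = (w.rhs[i - 1] - w.hseg[i] * Mc[i + 1]) / w.bfac[i - 1];
    }
  }
  // fused evaluation at samples 1..n for every channel
  env.resize((size_t)n * nc);
  int seg = 0;
  for (int t = 1; t <= n; ++t) {
    double xq = (double)t;
    while (seg < m - 2 && x[seg + 1] < xq) ++seg;
    double h = w.hseg[seg];
    double A = (x[seg + 1] - xq) / h, B = (xq - x[seg]) / h;
    double A3 = (A * A * A - A) * h * h / 6.0, B3 = (B * B * B - B) * h * h / 6.0;
    for (int c = 0; c < nc; ++c) {
      const double* yc = w.yk.data() + (size_t)c * m;
      const double* Mc = w.M.data() + (size_t)c * m;
      env[(size_t)c * n + t - 1] =
        A * yc[seg] + B * yc[seg + 1] + A3 * Mc[seg] + B3 * Mc[seg + 1];
    }
  }
}

// [[Rcpp::export]]
List envelope_mean_cpp(NumericMatrix values, NumericMatrix dirvecs) {
  const int n = values.nrow(), nc = values.ncol(), nd = dirvecs.nrow();
  const double* V = REAL(values);
  const double* D = REAL(dirvecs);
  NumericMatrix acc_mean(n, nc);
  NumericVector acc_amp(n);
  double* AM = REAL(acc_mean);
  double* AA = REAL(acc_amp);
  int n_used = 0;

  // Accumulate the two halves of the direction set separately and combine
  // commutatively at the end. The direction set pairs each vector in the
  // first half with its channel-1/2-swapped copy in the second half, so
  // this makes the envelope exactly equivariant under exchanging the first
  // two channels (the halves trade roles, and a + b == b + a in floating
  // point).
  const int h = nd - nd / 2;
  std::vector<double> am2((size_t)n * nc, 0.0), aa2(n, 0.0);

  EnvWork w;
  w.proj.resize(n);
  std::vector<double> emax, emin;

  for (int k = 0; k < nd; ++k) {
    const bool second = k >= h;
    double* AMk = second ? am2.data() : AM;
    double* AAk = second ? aa2.data() : AA;
    for (int t = 0; t < n; ++t) w.proj[t] = 0.0;
    for (int c = 0; c < nc; ++c) {
      const double* col = V + (size_t)c * n;
      const double dk = D[k + (size_t)c * nd];
      for (int t = 0; t < n; ++t) w.proj[t] += col[t] * dk;
    }
    find_extrema_cpp(w.proj, w.maxima, w.minima);
    if ((int)w.maxima.size() < 2 || (int)w.minima.size() < 2 ||
        w.maxima.size() + w.minima.size() < 4)
      continue;

    mirror_knots(w.maxima, n, w.knots, w.rows);
    spline_envelope(w.knots, w.maxima, w.rows, V, n, nc, w, emax);
    mirror_knots(w.minima, n, w.knots, w.rows);
    spline_envelope(w.knots, w.minima, w.rows, V, n, nc, w, emin);

    for (int t = 0; t < n; ++t) {
      double sq = 0.0;
      for (int c = 0; c < nc; ++c) {
        double mx = emax[(size_t)c * n + t], mn = emin[(size_t)c * n + t];
        AMk[t + (size_t)c * n] += mx + mn;
        double df = mx - mn;
        sq += df * df;
      }
      AAk[t] += std::sqrt(sq);
    }
    ++n_used;
  }

  if (n_used == 0) return List::create(Named("n_used") = 0);
  const double scale = 1.0 / (2.0 * n_used);
  for (size_t i = 0; i < (size_t)n * nc; ++i) AM[i] = (AM[i] + am2[i]) * scale;
  for (int t = 0; t < n; ++t) AA[t] = (AA[t] + aa2[t]) * scale;
  return List::create(Named("mean") = acc_mean,
                      Named("amplitude") = acc_amp,
                      Named("n_used") = n_used);
}
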