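#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Interior turning points of a sampled signal. Plateaus contribute a single
// extremum at their midpoint; endpoints are never reported.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& maxima,
                         std::vector<int>& minima) {
  maxima.clear();
  minima.clear();
  const int n = (int)x.size();
  if (n < 3) return;
  int last_sign = 0;   // sign of the most recent nonzero first difference
  int last_pos = 0;    // index where that difference ended
  for (int i = 1; i < n; ++i) {
    double d = x[i] - x[i - 1];
    int s = (d > 0.0) - (d < 0.0);
    if (s == 0) continue;
    if (last_sign > 0 && s < 0) {
      int idx = (last_pos + (i - 1)) / 2;  // plateau midpoint
      if (idx > 0 && idx < n - 1) maxima.push_back(idx);
    } else if (last_sign < 0 && s > 0) {
      int idx = (last_pos + (i - 1)) / 2;
      if (idx > 0 && idx < n - 1) minima.push_back(idx);
    }
    last_sign = s;
    last_pos = i;
  }
}

// Zero crossings: sign changes of the signal, exact zeros skipped.
static int count_zero_crossings(const std::vector<double>& x) {
  int count = 0, last = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    int s = (x[i] > 0.0) - (x[i] < 0.0);
    if (s == 0) continue;
    if (last != 0 && s != last) ++count;
    last = s;
  }
  return count;
}

// Natural cubic spline through (t, y), evaluated at the integers 0..n-1.
// Knots must be strictly increasing and bracket [0, n-1].
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& y,
                                int n, std::vector<double>& out) {
  const int k = (int)t.size();
  out.assign(n, 0.0);
  if (k == 2) {  // linear fallback
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = y[0] + slope * (i - t[0]);
    return;
  }
  // second derivatives m via Thomas algorithm, natural BC m0 = m_{k-1} = 0
  std::vector<double> h(k - 1), alpha(k, 0.0), l(k), mu(k), z(k), m(k);
  for (int i = 0; i < k - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  m[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) m[i] = z[i] - mu[i] * m[i + 1];
  // evaluate; walk the knot intervals once since eval points are sorted
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double tv = (double)i;
    while (seg < k - 2 && tv > t[seg + 1]) ++seg;
    double hs = t[seg + 1] - t[seg];
    double a = (t[seg + 1] - tv) / hs, b = (tv - t[seg]) / hs;
    out[i] = a * y[seg] + b * y[seg + 1] +
      ((a * a * a - a) * m[seg] + (b * b * b - b) * m[seg + 1]) * hs * hs / 6.0;
  }
}

// Mirror-extend up to two extrema of each kind past both ends, then collect
// the spline knots for one envelope.
static void mirrored_knots(const std::vector<int>& idx,
                           const std::vector<double>& x, int n,
                           std::vector<double>& t, std::vector<double>& y) {
  t.clear(); y.clear();
  const int k = (int)idx.size();
  int nl = std::min(2, k), nr = std::min(2, k);
  for (int i = nl - 1; i >= 0; --i) {          // left mirror about t = 0
    t.push_back(-(double)idx[i]);
    y.push_back(x[idx[i]]);
  }
  for (int i = 0; i < k; ++i) {
    t.push_back((double)idx[i]);
    y.push_back(x[idx[i]]);
  }
  for (int i = 0; i < nr; ++i) {               // right mirror about t = n-1
    t.push_back(2.0 * (n - 1) - (double)idx[k - 1 - i]);
    y.push_back(x[idx[k - 1 - i]]);
  }
}

// Envelope mean m(t) = (upper + lower)/2; returns false if fewer than one
// maximum or one minimum exists (the "cannot sift" condition).
static bool envelope_mean(const std::vector<double>& x,
                          std::vector<double>& m,
                          std::vector<int>& maxima,
                          std::vector<int>& minima) {
  const int n = (int)x.size();
  find_extrema(x, maxima, minima);
  if (maxima.empty() || minima.empty()) return false;
  std::vector<double> tu, yu, tl, yl, up, lo;
  mirrored_knots(maxima, x, n, tu, yu);
  mirrored_knots(minima, x, n, tl, yl);
  natural_spline_eval(tu, yu, n, up);
  natural_spline_eval(tl, yl, n, lo);
  m.resize(n);
  for (int i = 0; i < n; ++i) m[i] = 0.5 * (up[i] + lo[i]);
  return true;
}

static bool count_condition(const std::vector<double>& x) {
  std::vector<int> mx, mn;
  find_extrema(x, mx, mn);
  int ne = (int)(mx.size() + mn.size());
  int zc = count_zero_crossings(x);
  return std::abs(ne - zc) <= 1;
}

// Envelope-mean condition, evaluated on the interior spanned by the raw
// extrema (where the splines interpolate): the RMS of the envelope mean must
// not exceed env_tol times the mode's standard deviation. An RMS criterion
// is used because the pointwise envelope mean of a well-formed
// amplitude-modulated mode has heavy tails near envelope pinches.
static bool envelope_condition(const std::vector<double>& x,
                               const std::vector<double>& m,
                               const std::vector<int>& maxima,
                               const std::vector<int>& minima,
                               double env_tol) {
  int lo = (int)x.size(), hi = -1;
  if (!maxima.empty()) { lo = std::min(lo, maxima.front()); hi = std::max(hi, maxima.back()); }
  if (!minima.empty()) { lo = std::min(lo, minima.front()); hi = std::max(hi, minima.back()); }
  if (hi <= lo) return true;
  const int n = (int)x.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double var = 0.0;
  for (int i = 0; i < n; ++i) var += (x[i] - mean) * (x[i] - mean);
  double sdx = std::sqrt(var / (n - 1));
  if (sdx == 0.0) return true;
  double ms = 0.0;
  for (int i = lo; i <= hi; ++i) ms += m[i] * m[i];
  double rms = std::sqrt(ms / (hi - lo + 1));
  return rms <= env_tol * sdx;
}

// [[Rcpp::export(name = ".cpp_find_extrema")]]
List cpp_find_extrema(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> mx, mn;
  find_extrema(xv, mx, mn);
  IntegerVector rmx(mx.size()), rmn(mn.size());
  for (size_t i = 0; i < mx.size(); ++i) rmx[i] = mx[i] + 1;
  for (size_t i = 0; i < mn.size(); ++i) rmn[i] = mn[i] + 1;
  return List::create(_["maxima"] = rmx, _["minima"] = rmn);
}

// [[Rcpp::export(name = ".cpp_zero_crossings")]]
int cpp_zero_crossings(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  return count_zero_crossings(xv);
}

// [[Rcpp::export(name = ".cpp_envelope_mean")]]
List cpp_envelope_mean(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end()), m;
  std::vector<int> mx, mn;
  bool ok = envelope_mean(xv, m, mx, mn);
  if (!ok)
    return List::create(_["ok"] = false, _["mean"] = R_NilValue);
  return List::create(_["ok"] = true, _["mean"] = NumericVector(m.begin(), m.end()));
}

// [[Rcpp::export(name = ".cpp_is_imf")]]
bool cpp_is_imf(NumericVector x, double env_tol) {
  std::vector<double> xv(x.begin(), x.end()), m;
  std::vector<int> mx, mn;
  if (!count_condition(xv)) return false;
  if (!envelope_mean(xv, m, mx, mn)) return false;
  return envelope_condition(xv, m, mx, mn, env_tol);
}

// Full sifting decomposition. Returns modes (n x J matrix, possibly J = 0),
// the residual, and the sift count per mode.
// [[Rcpp::export(name = ".cpp_emd")]]
List cpp_emd(NumericVector x, int max_modes, int max_sifts,
             double stop_sd, double env_tol) {
  const int n = x.size();
  std::vector<double> residual(x.begin(), x.end());
  std::vector<std::vector<double> > modes;
  std::vector<int> sift_counts;
  double xmin = x[0], xmax = x[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, (double)x[i]);
    xmax = std::max(xmax, (double)x[i]);
  }
  const double range = xmax - xmin;

  for (int j = 0; j < max_modes; ++j) {
    std::vector<int> mx, mn;
    find_extrema(residual, mx, mn);
    if ((int)(mx.size() + mn.size()) < 2) break;  // non-oscillating trend
    double rmin = residual[0], rmax = residual[0];
    for (int i = 1; i < n; ++i) {
      rmin = std::min(rmin, residual[i]);
      rmax = std::max(rmax, residual[i]);
    }
    if (rmax - rmin < 1e-12 * range) break;  // numerically exhausted

    std::vector<double> h(residual), m;
    if (!envelope_mean(h, m, mx, mn)) break;
    int sifts = 0;
    for (int s = 1; s <= max_sifts; ++s) {
      sifts = s;
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        num += m[i] * m[i];
        den += h[i] * h[i];
        h[i] -= m[i];
      }
      double sd = (den > 0.0) ? num / den : 0.0;
      if (s == max_sifts) break;
      std::vector<int> mx2, mn2;
      std::vector<double> m2;
      if (!envelope_mean(h, m2, mx2, mn2)) break;  // extrema exhausted
      bool count_ok = count_condition(h);
      bool env_ok = envelope_condition(h, m2, mx2, mn2, env_tol);
      if (count_ok && env_ok && sd < stop_sd) break;
      m.swap(m2);
    }
    modes.push_back(h);
    sift_counts.push_back(sifts);
    for (int i = 0; i < n; ++i) residual[i] -= h[i];
  }

  NumericMatrix mm(n, (int)modes.size());
  for (size_t j = 0; j < modes.size(); ++j)
    for (int i = 0; i < n; ++i) mm(i, (int)j) = modes[j][i];
  return List::create(
    _["modes"] = mm,
    _["residual"] = NumericVector(residual.begin(), residual.end()),
    _["sifts"] = IntegerVector(sift_counts.begin(), sift_counts.end()));
}
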