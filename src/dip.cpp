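// Hartigan-Hartigan dip statistic.
//
// The dip of an empirical CDF F_n is the minimax sup-distance to the nearest
// unimodal CDF: convex below the mode, concave above it, with an atom
// permitted at the mode. It is computed by bisection on the half-width d of
// a band around F_n, testing whether a unimodal CDF can thread the band.
//
// Feasibility enumerates mode placements. For a mode at a data point the
// left limit and the value become knots of the convex and concave chains,
// whose band feasibility is checked through the greatest convex minorant of
// the upper bounds; the junction uses extremal knot values from pairwise
// slope bounds (any convex nondecreasing g through bands [L_t, U_t]
// satisfies g(m) >= L_t + max_r (L_t - U_r)/(x_t - x_r) (m - x_t)). For a
// mode inside a support gap, both gap endpoints and interior positions are
// tested, the latter by ternary search on the convex piecewise-linear
// infeasibility gap built from those envelopes and the gap band caps.
// The implementation is validated in the tests against frozen values from an
// exact linear-programming minimisation over piecewise-linear unimodal CDFs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Side {
  std::vector<double> x, L, U, maxsl;
  int amax = 0, apmax = 0;  // feasible full-band / upper-only-terminal prefixes

  void prefix_feasible() {
    const int m = (int)x.size();
    amax = apmax = 0;
    std::vector<int> hull;
    bool ok_full_prev = true;
    for (int t = 0; t < m; ++t) {
      while ((int)hull.size() >= 2) {
        int i = hull[hull.size() - 2], j = hull.back();
        if ((U[t] - U[i]) * (x[j] - x[i]) <= (U[j] - U[i]) * (x[t] - x[i]))
          hull.pop_back();
        else
          break;
      }
      bool ok = true;
      if (!hull.empty()) {
        int h = hull.back();
        double x0 = x[h], y0 = U[h], x1 = x[t], y1 = U[t];
        for (int i = h + 1; i < t; ++i) {
          double yi = y0 + (y1 - y0) * (x[i] - x0) / (x1 - x0);
          if (yi < L[i] - 1e-13) { ok = false; break; }
        }
      }
      hull.push_back(t);
      if (!(ok && ok_full_prev)) break;
      apmax = t + 1;
      if (U[t] >= L[t] - 1e-13) amax = t + 1; else ok_full_prev = false;
    }
  }

  void pair_lines() {
    const int m = (int)x.size();
    maxsl.assign(m, 0.0);
    for (int t = 1; t < m; ++t) {
      double best = 0.0;
      for (int r = 0; r < t; ++r) {
        double s = (L[t] - U[r]) / (x[t] - x[r]);
        if (s > best) best = s;
      }
      maxsl[t] = best;
    }
  }

  // pairwise lower bound on the chain's extension value at position pos,
  // using points 0..upto-1
  double env(int upto, double pos) const {
    if (upto <= 0) return 0.0;
    double best = 0.0;
    for (int t = 0; t < upto; ++t) {
      double v = L[t] + maxsl[t] * (pos - x[t]);
      if (v > best) best = v;
    }
    return best;
  }
};

bool feasible(const std::vector<double>& xs, const std::vector<double>& lo,
              const std::vector<double>& hi, double n, double d) {
  const int m_u = (int)xs.size();
  Side fwd, rev;
  fwd.x = xs;
  fwd.L.resize(m_u); fwd.U.resize(m_u);
  rev.x.resize(m_u); rev.L.resize(m_u); rev.U.resize(m_u);
  for (int i = 0; i < m_u; ++i) {
    fwd.L[i] = std::max(hi[i] / n - d, 0.0);
    fwd.U[i] = std::min((lo[i] - 1.0) / n + d, 1.0);
  }
  for (int i = 0; i < m_u; ++i) {
    rev.x[i] = -xs[m_u - 1 - i];
    rev.L[i] = std::max(1.0 - fwd.U[m_u - 1 - i], 0.0);
    rev.U[i] = std::min(1.0 - fwd.L[m_u - 1 - i], 1.0);
  }
  fwd.prefix_feasible();
  rev.prefix_feasible();
  const int bmin = m_u - rev.amax + 1;
  const int bpmin = m_u - rev.apmax + 1;
  if (fwd.amax == m_u || bmin == 1) return true;  // mode beyond the data

  fwd.pair_lines();
  rev.pair_lines();
  const double eps = 1e-13;
  // A_at(s, m): min left limit at m from prefix of s points (1-based count)
  auto A_at = [&](int s, double m) { return fwd.env(s, m); };
  // B_at(s1, m): max value at m from suffix starting at point s1 (1-based)
  auto B_at = [&](int s1, double m) {
    return 1.0 - rev.env(m_u - s1 + 1, -m);
  };

  // mode at a data point u (atom allowed there)
  for (int u = std::max(1, bpmin); u <= fwd.apmax; ++u) {
    int i = u - 1;
    double vcap = hi[i] / n + d;
    double lmin = (u > 1) ? A_at(u - 1, xs[i]) : 0.0;
    double vmax = (u < m_u) ? std::min(vcap, B_at(u + 1, xs[i])) : vcap;
    if (lmin <= vmax + eps) return true;
  }

  // mode in the gap between points s and s+1
  int s_lo = std::max(1, bmin - 1);
  int s_hi = std::min(fwd.amax, m_u - 1);
  for (int s = s_lo; s <= s_hi; ++s) {
    if (s + 1 < bmin) continue;
    double c = hi[s - 1] / n;
    double cap_hi = c + d;
    double cap_lo = std::max(c - d, 0.0);
    double a = xs[s - 1], b = xs[s];
    auto phi = [&](double m) {
      double A = A_at(s, m);
      double B = B_at(s + 1, m);
      return std::max(A - B, std::max(A - cap_hi, cap_lo - B));
    };
    if (phi(a) <= eps || phi(b) <= eps) return true;
    // necessary conditions for an interior minimum (A, B nondecreasing in m)
    if (A_at(s, a) > cap_hi + eps) continue;
    if (cap_lo > B_at(s + 1, b) + eps) continue;
    if (A_at(s, a) > B_at(s + 1, b) + eps) continue;
    double x1 = a, x2 = b;
    for (int it = 0; it < 48 && (x2 - x1) > 1e-12 * std::max(1.0, std::abs(b));
         ++it) {
      double m1 = x1 + (x2 - x1) / 3.0;
      double m2 = x2 - (x2 - x1) / 3.0;
      double f1 = phi(m1), f2 = phi(m2);
      if (std::min(f1, f2) <= eps) return true;
      if (f1 <= f2) x2 = m2; else x1 = m1;
    }
  }
  return false;
}

} // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::sort(v.begin(), v.end());
  const double n = (double)v.size();
  std::vector<double> xs, lo, hi;
  for (size_t i = 0; i < v.size(); ++i) {
    if (xs.empty() || v[i] != xs.back()) {
      xs.push_back(v[i]);
      lo.push_back((double)(i + 1));
      hi.push_back((double)(i + 1));
    } else {
      hi.back() = (double)(i + 1);
    }
  }
  if (xs.size() < 2) return 0.0;
  if (feasible(xs, lo, hi, n, 0.0)) return 0.0;
  double lod = 0.0, hid = 0.25;
  for (int it = 0; it < 52 && (hid - lod) > 1e-11; ++it) {
    double mid = 0.5 * (lod + hid);
    if (feasible(xs, lo, hi, n, mid)) hid = mid; else lod = mid;
  }
  return hid;
}

// [[Rcpp::export(name = ".dip_stat_many_cpp")]]
NumericVector dip_stat_many_cpp(NumericMatrix xs) {
  // dip of each column (used for bootstrap null distributions)
  NumericVector out(xs.ncol());
  for (int j = 0; j < xs.ncol(); ++j) {
    NumericVector col = xs(_, j);
    out[j] = dip_stat_cpp(col);
  }
  return out;
}
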