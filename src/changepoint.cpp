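#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Segment cost = within-segment residual sum of squares under a constant
// mean.  Costs are O(1) via cumulative sums of the globally centered trace
// (centering keeps the S2 - S^2/n cancellation benign for mm-scale COD
// values); the cumulative sums themselves are Kahan-compensated.
namespace {

struct CostTable {
  std::vector<double> cs;   // cs[i]  = sum of centered y[0..i-1]
  std::vector<double> cs2;  // cs2[i] = sum of centered y[0..i-1]^2
  explicit CostTable(const NumericVector& y) {
    const int T = y.size();
    double mean = 0.0, comp = 0.0;
    for (int i = 0; i < T; ++i) {
      double t = y[i] - comp;
      double s = mean + t;
      comp = (s - mean) - t;
      mean = s;
    }
    mean /= T;
    cs.assign(T + 1, 0.0);
    cs2.assign(T + 1, 0.0);
    double a = 0.0, ca = 0.0, b = 0.0, cb = 0.0;
    for (int i = 0; i < T; ++i) {
      const double v = y[i] - mean;
      double t1 = v - ca;
      double s1 = a + t1;
      ca = (s1 - a) - t1;
      a = s1;
      cs[i + 1] = a;
      double t2 = v * v - cb;
      double s2 = b + t2;
      cb = (s2 - b) - t2;
      b = s2;
      cs2[i + 1] = b;
    }
  }
  // RSS of y[i..j], 0-based inclusive
  inline double operator()(int i, int j) const {
    const int n = j - i + 1;
    const double S = cs[j + 1] - cs[i];
    const double S2 = cs2[j + 1] - cs2[i];
    double c = S2 - S * S / n;
    return c > 0.0 ? c : 0.0;
  }
};

}  // namespace

// Segment-neighborhood dynamic programming: exact E_min(q) and one
// optimizing changepoint set for every q = 0..nmax.  O(nmax * T^2).
// Ties broken toward the earlier boundary (ascending scan, strict <).
// [[Rcpp::export]]
List cpp_segneigh(NumericVector y, int nmax) {
  const int T = y.size();
  if (T < 1) stop("empty trace");
  if (nmax < 0 || nmax >= T) stop("nmax out of range");
  CostTable cost(y);

  NumericMatrix F(nmax + 1, T);       // F(q, t): min cost of y[0..t], q cps
  IntegerMatrix B(nmax + 1, T);       // start index of last segment
  const double INF = std::numeric_limits<double>::infinity();

  for (int t = 0; t < T; ++t) {
    F(0, t) = cost(0, t);
    B(0, t) = 0;
  }
  for (int q = 1; q <= nmax; ++q) {
    for (int t = 0; t < T; ++t) {
      if (t < q) { F(q, t) = INF; B(q, t) = -1; continue; }
      double best = INF;
      int arg = -1;
      for (int s = q - 1; s < t; ++s) {   // last segment is y[s+1..t]
        const double v = F(q - 1, s) + cost(s + 1, t);
        if (v < best) { best = v; arg = s + 1; }
      }
      F(q, t) = best;
      B(q, t) = arg;
    }
    Rcpp::checkUserInterrupt();
  }

  NumericVector emin(nmax + 1);
  List cps(nmax + 1);
  for (int q = 0; q <= nmax; ++q) {
    emin[q] = F(q, T - 1);
    IntegerVector cp(q);
    int t = T - 1;
    for (int lev = q; lev >= 1; --lev) {
      const int s = B(lev, t);        // first index of last segment
      cp[lev - 1] = s;                // boundary before element s (0-based)
      t = s - 1;
    }
    cps[q] = cp;
  }
  return List::create(_["emin"] = emin, _["cps"] = cps);
}

// PELT: minimize sum of segment RSS + beta * (#changepoints), exact with
// linear-time pruning (K = 0 is valid for the RSS cost).  Ties broken
// toward the earlier boundary.
// [[Rcpp::export]]
List cpp_pelt(NumericVector y, double beta) {
  const int T = y.size();
  if (T < 1) stop("empty trace");
  if (beta < 0) stop("penalty must be >= 0");
  CostTable cost(y);
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> F(T + 1);
  std::vector<int> last(T + 1, 0);
  F[0] = -beta;
  std::vector<int> cand;
  cand.reserve(64);
  cand.push_back(0);
  std::vector<double> fit(T + 1);     // F[s] + cost(s, t-1), reused for pruning

  for (int t = 1; t <= T; ++t) {
    double best = INF;
    int arg = 0;
    for (size_t k = 0; k < cand.size(); ++k) {
      const int s = cand[k];
      const double v = F[s] + cost(s, t - 1);
      fit[s] = v;
      if (v + beta < best) { best = v + beta; arg = s; }
    }
    F[t] = best;
    last[t] = arg;
    size_t keep = 0;
    for (size_t k = 0; k < cand.size(); ++k) {
      const int s = cand[k];
      if (fit[s] <= F[t]) cand[keep++] = s;
    }
    cand.resize(keep);
    cand.push_back(t);
  }

  std::vector<int> cps;
  int t = T;
  while (t > 0) {
    const int s = last[t];
    if (s > 0) cps.push_back(s);
    t = s;
  }
  std::reverse(cps.begin(), cps.end());
  const int n = static_cast<int>(cps.size());
  const double E = F[T] - beta * n;   // unpenalized total RSS
  return List::create(_["cps"] = IntegerVector(cps.begin(), cps.end()),
                      _["E"] = E, _["n"] = n);
}
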