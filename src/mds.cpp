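#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Unit-weight least-squares isotonic (non-decreasing) regression, in place.
// Classic pool-adjacent-violators with block merging.
static void pava(std::vector<double>& y, std::vector<double>& level,
                 std::vector<double>& weight, std::vector<int>& count) {
  const int n = (int)y.size();
  if (n < 2) return;
  if ((int)level.size() < n) {
    level.resize(n); weight.resize(n); count.resize(n);
  }
  int k = 0;
  for (int i = 0; i < n; ++i) {
    level[k] = y[i]; weight[k] = 1.0; count[k] = 1; ++k;
    while (k > 1 && level[k - 2] > level[k - 1]) {
      double w = weight[k - 2] + weight[k - 1];
      level[k - 2] = (weight[k - 2] * level[k - 2] + weight[k - 1] * level[k - 1]) / w;
      weight[k - 2] = w;
      count[k - 2] += count[k - 1];
      --k;
    }
  }
  int pos = 0;
  for (int b = 0; b < k; ++b)
    for (int c = 0; c < count[b]; ++c) y[pos++] = level[b];
}

// Monotone fit of d against a dissimilarity ordering, Kruskal primary ties:
// within each tie block the configuration distances are sorted ascending, so
// tied dissimilarities are unconstrained among themselves.
// ord: pair indices (0-based) sorted by dissimilarity; bstart: block starts
// into ord (length nblock + 1, last element = np). idx persists between
// calls: when full_sort is false the previous order is refined by insertion
// sort, which is near-linear because configurations change slowly between
// majorization steps.
struct PavaScratch {
  std::vector<double> level, weight;
  std::vector<int> count;
};

static void monotone_primary(const std::vector<double>& d,
                             const IntegerVector& ord,
                             const IntegerVector& bstart,
                             std::vector<int>& idx,
                             std::vector<double>& y,
                             std::vector<double>& dhat,
                             PavaScratch& ps,
                             bool full_sort) {
  const int np = (int)d.size();
  const int nb = bstart.size() - 1;
  if (full_sort) {
    for (int t = 0; t < np; ++t) idx[t] = ord[t];
    for (int b = 0; b < nb; ++b) {
      int s = bstart[b], e = bstart[b + 1];
      if (e - s > 1)
        std::sort(idx.begin() + s, idx.begin() + e,
                  [&](int a, int c) { return d[a] < d[c]; });
    }
  } else {
    // near-sorted refinement; fall back to std::sort for blocks where the
    // shift budget is exceeded (early iterations of random starts)
    for (int b = 0; b < nb; ++b) {
      int s = bstart[b], e = bstart[b + 1];
      long budget = 4L * (e - s) + 64;
      long shifts = 0;
      bool ok = true;
      for (int t = s + 1; t < e; ++t) {
        int v = idx[t];
        double dv = d[v];
        int u = t - 1;
        while (u >= s && d[idx[u]] > dv) { idx[u + 1] = idx[u]; --u; ++shifts; }
        idx[u + 1] = v;
        if (shifts > budget) { ok = false; break; }
      }
      if (!ok)
        std::sort(idx.begin() + s, idx.begin() + e,
                  [&](int a, int c) { return d[a] < d[c]; });
    }
  }
  for (int t = 0; t < np; ++t) y[t] = d[idx[t]];
  pava(y, ps.level, ps.weight, ps.count);
  for (int t = 0; t < np; ++t) dhat[idx[t]] = y[t];
}

// [[Rcpp::export]]
NumericVector cpp_monotone_fit(NumericVector d, IntegerVector ord,
                               IntegerVector bstart) {
  const int np = d.size();
  std::vector<double> dv(d.begin(), d.end()), y(np), dhat(np);
  std::vector<int> idx(np);
  PavaScratch ps;
  monotone_primary(dv, ord, bstart, idx, y, dhat, ps, true);
  return NumericVector(dhat.begin(), dhat.end());
}

// SMACOF-style minimization of Kruskal stress-1 with monotone disparities
// (nonmetric MDS), optionally blended with a metric least-squares target on
// low-dissimilarity pairs (hybrid MDS). Guttman transform updates with
// over-relaxation (step doubling) and fallback to the plain transform when a
// relaxed step overshoots, so the recorded stress sequence is non-increasing.
//
// Xinit: n x 2 start configuration.
// pi, pj: 0-based site indices of each pair (dist object order).
// ord, bstart: dissimilarity ordering and tie blocks (see monotone_primary).
// metric_idx: 0-based indices of pairs entering the metric term; empty for
//   pure NMDS. metric_delta: their dissimilarities. metric_weight in [0,1].
// [[Rcpp::export]]
List cpp_mds_engine(NumericMatrix Xinit, IntegerVector pi, IntegerVector pj,
                    IntegerVector ord, IntegerVector bstart,
                    IntegerVector metric_idx, NumericVector metric_delta,
                    double metric_weight, int max_iter, double tol) {
  const int n = Xinit.nrow();
  const int np = pi.size();
  const int nm = metric_idx.size();
  const bool hybrid = (nm > 0 && metric_weight > 0.0);

  NumericMatrix X = clone(Xinit);
  NumericMatrix T(n, 2), Xbest = clone(X);
  std::vector<double> d(np), dhat(np), target(np), y(np);
  std::vector<int> idx(np);
  PavaScratch ps;
  std::vector<double> trace;
  trace.reserve(128);
  double* x0 = REAL(X); double* x1 = x0 + n;
  double* t0p = REAL(T); double* t1p = t0p + n;
  const int* pip = INTEGER(pi); const int* pjp = INTEGER(pj);

  double best_stress = R_PosInf, prev = R_PosInf;
  bool converged = false, relaxed_last = false, have_T = false;
  int evals = 0;

  while (evals < max_iter) {
    ++evals;
    // configuration distances
    double ssd = 0.0;
    for (int k = 0; k < np; ++k) {
      double dx = x0[pip[k]] - x0[pjp[k]];
      double dy = x1[pip[k]] - x1[pjp[k]];
      double dk = std::sqrt(dx * dx + dy * dy);
      d[k] = dk;
      ssd += dk * dk;
    }
    if (ssd < 1e-300) { // collapsed configuration: degenerate
      trace.push_back(NA_REAL);
      break;
    }
    // monotone disparities (primary ties)
    monotone_primary(d, ord, bstart, idx, y, dhat, ps, evals <= 2);
    // targets: blend with through-origin linear fit on metric pairs
    for (int k = 0; k < np; ++k) target[k] = dhat[k];
    if (hybrid) {
      double num = 0.0, den = 0.0;
      for (int t = 0; t < nm; ++t) {
        int k = metric_idx[t];
        num += d[k] * metric_delta[t];
        den += metric_delta[t] * metric_delta[t];
      }
      double b = (den > 0.0) ? num / den : 0.0;
      for (int t = 0; t < nm; ++t) {
        int k = metric_idx[t];
        target[k] = (1.0 - metric_weight) * dhat[k] +
                    metric_weight * b * metric_delta[t];
      }
    }
    // stress-1 against targets
    double sse = 0.0;
    for (int k = 0; k < np; ++k) {
      double r = d[k] - target[k];
      sse += r * r;
    }
    double stress = std::sqrt(sse / ssd);
    if (stress > prev && relaxed_last && have_T) {
      // over-relaxed step overshot: retry from the plain transform
      for (int i = 0; i < n; ++i) { x0[i] = t0p[i]; x1[i] = t1p[i]; }
      relaxed_last = false;
      continue;
    }
    trace.push_back(stress);
    if (stress < best_stress) {
      best_stress = stress;
      Xbest = clone(X);
    }
    if (stress < 1e-14) { converged = true; break; }
    if (R_finite(prev)) {
      double change = prev - stress;
      if (change >= 0.0 && change < tol * std::max(prev, 1e-12)) {
        converged = true;
        break;
      }
      if (change < 0.0) break; // plain step increased stress: stalled
    }
    prev = stress;
    // Guttman transform T = (1/n) B(X) X, centered
    for (int i = 0; i < n; ++i) { t0p[i] = 0.0; t1p[i] = 0.0; }
    for (int k = 0; k < np; ++k) {
      if (d[k] <= 0.0) continue;
      double ratio = target[k] / d[k];
      int a = pip[k], b = pjp[k];
      double dx = ratio * (x0[a] - x0[b]);
      double dy = ratio * (x1[a] - x1[b]);
      t0p[a] += dx; t1p[a] += dy;
      t0p[b] -= dx; t1p[b] -= dy;
    }
    double m0 = 0.0, m1 = 0.0;
    for (int i = 0; i < n; ++i) {
      t0p[i] /= n; t1p[i] /= n;
      m0 += t0p[i]; m1 += t1p[i];
    }
    m0 /= n; m1 /= n;
    // relaxed update: X <- 2 T - X (both centered)
    for (int i = 0; i < n; ++i) {
      double ta = t0p[i] - m0, tb = t1p[i] - m1;
      t0p[i] = ta; t1p[i] = tb;
      x0[i] = 2.0 * ta - x0[i];
      x1[i] = 2.0 * tb - x1[i];
    }
    have_T = true;
    relaxed_last = true;
  }

  return List::create(_["coordinates"] = Xbest,
                      _["stress"] = best_stress,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = (int)trace.size(),
                      _["converged"] = converged);
}
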