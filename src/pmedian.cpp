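#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double dist2d(double ax, double ay, double bx, double by) {
  double dx = ax - bx, dy = ay - by;
  return std::sqrt(dx * dx + dy * dy);
}

// Demand-point x site distance matrix (m x n).
// [[Rcpp::export]]
NumericMatrix cpp_cross_dist(NumericMatrix grid, NumericMatrix coords) {
  const int m = grid.nrow(), n = coords.nrow();
  NumericMatrix D(m, n);
  for (int f = 0; f < n; ++f) {
    double cx = coords(f, 0), cy = coords(f, 1);
    for (int i = 0; i < m; ++i)
      D(i, f) = dist2d(grid(i, 0), grid(i, 1), cx, cy);
  }
  return D;
}

// Sum over demand points of distance to nearest selected site, computed from
// coordinates directly: O(m * p) time, O(p) extra memory, no m x n matrix.
// sel is 1-based.
// [[Rcpp::export]]
double cpp_pmedian_objective(NumericMatrix coords, NumericMatrix grid,
                             IntegerVector sel) {
  const int m = grid.nrow(), p = sel.size();
  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    double gx = grid(i, 0), gy = grid(i, 1);
    double best = R_PosInf;
    for (int t = 0; t < p; ++t) {
      int f = sel[t] - 1;
      double d = dist2d(gx, gy, coords(f, 0), coords(f, 1));
      if (d < best) best = d;
    }
    total += best;
  }
  return total;
}

static double obj_from_D(const NumericMatrix& D, const std::vector<int>& sel) {
  const int m = D.nrow();
  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    for (size_t t = 0; t < sel.size(); ++t) {
      double d = D(i, sel[t]);
      if (d < best) best = d;
    }
    total += best;
  }
  return total;
}

// nearest / second-nearest bookkeeping for fast swap evaluation
struct Near {
  std::vector<double> d1, d2;
  std::vector<int> n1, n2;
};

static void near_rescan_row(const NumericMatrix& D, const std::vector<int>& sel,
                            int i, Near& nr) {
  double b1 = R_PosInf, b2 = R_PosInf;
  int s1 = -1, s2 = -1;
  for (size_t t = 0; t < sel.size(); ++t) {
    double d = D(i, sel[t]);
    if (d < b1) { b2 = b1; s2 = s1; b1 = d; s1 = sel[t]; }
    else if (d < b2) { b2 = d; s2 = sel[t]; }
  }
  nr.d1[i] = b1; nr.n1[i] = s1; nr.d2[i] = b2; nr.n2[i] = s2;
}

static void near_init(const NumericMatrix& D, const std::vector<int>& sel,
                      Near& nr) {
  const int m = D.nrow();
  nr.d1.assign(m, 0.0); nr.d2.assign(m, 0.0);
  nr.n1.assign(m, -1); nr.n2.assign(m, -1);
  for (int i = 0; i < m; ++i) near_rescan_row(D, sel, i, nr);
}

// apply swap: site `f` enters, `s` leaves; update nearest structures
static void near_swap(const NumericMatrix& D, const std::vector<int>& sel,
                      int f, int s, Near& nr) {
  const int m = D.nrow();
  for (int i = 0; i < m; ++i) {
    if (nr.n1[i] == s || nr.n2[i] == s) {
      near_rescan_row(D, sel, i, nr);
    } else {
      double dif = D(i, f);
      if (dif < nr.d1[i]) {
        nr.d2[i] = nr.d1[i]; nr.n2[i] = nr.n1[i];
        nr.d1[i] = dif; nr.n1[i] = f;
      } else if (dif < nr.d2[i]) {
        nr.d2[i] = dif; nr.n2[i] = f;
      }
    }
  }
}

// Vertex-substitution (Teitz-Bart style) local search with Resende-Werneck
// swap evaluation. Modifies sel in place; returns final objective.
static double swap_search(const NumericMatrix& D, std::vector<int>& sel,
                          std::vector<char>& inSel, int max_pass = 500) {
  const int m = D.nrow(), n = D.ncol();
  const int p = (int)sel.size();
  if (p >= n) return obj_from_D(D, sel);
  Near nr;
  near_init(D, sel, nr);
  std::vector<double> loss(n, 0.0);
  for (int pass = 0; pass < max_pass; ++pass) {
    double best_delta = -1e-12;
    int best_f = -1, best_s = -1;
    for (int f = 0; f < n; ++f) {
      if (inSel[f]) continue;
      double gain = 0.0;
      for (size_t t = 0; t < sel.size(); ++t) loss[sel[t]] = 0.0;
      for (int i = 0; i < m; ++i) {
        double dif = D(i, f);
        if (dif < nr.d1[i]) gain += nr.d1[i] - dif;
        double w = std::min(nr.d2[i], dif) - std::min(nr.d1[i], dif);
        loss[nr.n1[i]] += w;
      }
      for (size_t t = 0; t < sel.size(); ++t) {
        int s = sel[t];
        double delta = loss[s] - gain; // change in objective
        if (delta < best_delta ||
            (delta == best_delta && best_f >= 0 &&
             (f < best_f || (f == best_f && s < best_s)))) {
          best_delta = delta; best_f = f; best_s = s;
        }
      }
    }
    if (best_f < 0) break;
    // apply swap
    for (size_t t = 0; t < sel.size(); ++t)
      if (sel[t] == best_s) { sel[t] = best_f; break; }
    inSel[best_s] = 0; inSel[best_f] = 1;
    near_swap(D, sel, best_f, best_s, nr);
  }
  return obj_from_D(D, sel);
}

// Fast vertex-substitution local search with incrementally maintained swap
// structures (gain per candidate, per-(candidate, incumbent) loss table),
// after Resende & Werneck's fast-swap design. Dt is the transposed distance
// matrix (n x m) for cache-friendly per-point updates. Falls back to the
// pass-based search above when the n x n loss table would be too large.
static double swap_search_fast(const NumericMatrix& D, const NumericMatrix& Dt,
                               std::vector<int>& sel, std::vector<char>& inSel,
                               int max_swaps = 5000) {
  const int m = D.nrow(), n = D.ncol();
  const int p = (int)sel.size();
  if (p >= n) return obj_from_D(D, sel);
  Near nr;
  std::vector<double> gain(n);
  std::vector<double> Et((size_t)n * n); // Et[s + n*f]
  int since_rebuild = 0;

  // build gain and Et from scratch
  auto build = [&]() {
    near_init(D, sel, nr);
    std::fill(gain.begin(), gain.end(), 0.0);
    std::fill(Et.begin(), Et.end(), 0.0);
    for (int f = 0; f < n; ++f) {
      double g = 0.0;
      double* col = &Et[(size_t)n * f];
      for (int i = 0; i < m; ++i) {
        double dif = D(i, f);
        if (dif < nr.d1[i]) g += nr.d1[i] - dif;
        double w = std::min(nr.d2[i], dif) - std::min(nr.d1[i], dif);
        if (w > 0.0) col[nr.n1[i]] += w;
      }
      gain[f] = g;
    }
    since_rebuild = 0;
  };
  build();

  for (int swaps = 0; swaps < max_swaps; ++swaps) {
    double best_delta = -1e-12;
    int best_f = -1, best_s = -1;
    for (int f = 0; f < n; ++f) {
      if (inSel[f]) continue;
      double g = gain[f];
      if (g <= -best_delta) continue; // delta >= -g cannot beat best
      const double* col = &Et[(size_t)n * f];
      for (size_t t = 0; t < sel.size(); ++t) {
        int s = sel[t];
        double delta = col[s] - g;
        if (delta < best_delta) { best_delta = delta; best_f = f; best_s = s; }
      }
    }
    if (best_f < 0) break;
    // apply swap best_f in, best_s out, updating structures per changed point
    for (size_t t = 0; t < sel.size(); ++t)
      if (sel[t] == best_s) { sel[t] = best_f; break; }
    inSel[best_s] = 0; inSel[best_f] = 1;
    if (++since_rebuild >= 50) { build(); continue; } // cap float drift
    for (int i = 0; i < m; ++i) {
      double d1 = nr.d1[i], d2 = nr.d2[i];
      int n1 = nr.n1[i], n2 = nr.n2[i];
      // new nearest pair after the swap
      double nd1, nd2; int nn1, nn2;
      if (n1 == best_s || n2 == best_s) {
        double b1 = R_PosInf, b2 = R_PosInf; int s1 = -1, s2 = -1;
        const double* row = &Dt(0, i);
        for (size_t t = 0; t < sel.size(); ++t) {
          double d = row[sel[t]];
          if (d < b1) { b2 = b1; s2 = s1; b1 = d; s1 = sel[t]; }
          else if (d < b2) { b2 = d; s2 = sel[t]; }
        }
        nd1 = b1; nn1 = s1; nd2 = b2; nn2 = s2;
      } else {
        double dif = Dt(best_f, i);
        nd1 = d1; nd2 = d2; nn1 = n1; nn2 = n2;
        if (dif < d1) { nd2 = d1; nn2 = n1; nd1 = dif; nn1 = best_f; }
        else if (dif < d2) { nd2 = dif; nn2 = best_f; }
      }
      if (nd1 == d1 && nd2 == d2 && nn1 == n1) {
        nr.n2[i] = nn2; nr.d2[i] = nd2; // may still have changed when equal
        continue;
      }
      const double* row = &Dt(0, i);
      for (int f = 0; f < n; ++f) {
        double dif = row[f];
        if (dif < d1) gain[f] -= d1 - dif;
        if (dif < nd1) gain[f] += nd1 - dif;
        double wold = std::min(d2, dif) - std::min(d1, dif);
        if (wold > 0.0) Et[(size_t)n * f + n1] -= wold;
        double wnew = std::min(nd2, dif) - std::min(nd1, dif);
        if (wnew > 0.0) Et[(size_t)n * f + nn1] += wnew;
      }
      nr.d1[i] = nd1; nr.d2[i] = nd2; nr.n1[i] = nn1; nr.n2[i] = nn2;
    }
  }
  return obj_from_D(D, sel);
}

// Lazy-greedy completion of a partial selection up to size p.
// Gains are submodular, so stale heap entries only overestimate. With
// stale_tol > 0 an entry computed up to stale_tol additions ago is accepted
// without re-evaluation (approximate greedy, used for the randomized starts
// whose role is only to seed the local search); stale_tol = 0 is exact.
static void greedy_complete(const NumericMatrix& D, int p,
                            std::vector<int>& sel, std::vector<char>& inSel,
                            int stale_tol = 0) {
  const int m = D.nrow(), n = D.ncol();
  if ((int)sel.size() == 0) {
    // first site: minimum column sum, ties -> lowest index
    double best = R_PosInf; int bf = 0;
    for (int f = 0; f < n; ++f) {
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += D(i, f);
      if (s < best) { best = s; bf = f; }
    }
    sel.push_back(bf); inSel[bf] = 1;
  }
  std::vector<double> d1(m);
  for (int i = 0; i < m; ++i) {
    double b = R_PosInf;
    for (size_t t = 0; t < sel.size(); ++t) b = std::min(b, D(i, sel[t]));
    d1[i] = b;
  }
  // heap of (gain, -f, stamp); stamp = |sel| when gain was computed
  typedef std::pair<std::pair<double, int>, int> Entry; // ((gain, -f), stamp)
  std::priority_queue<Entry> heap;
  for (int f = 0; f < n; ++f) {
    if (inSel[f]) continue;
    double g = 0.0;
    for (int i = 0; i < m; ++i)
      if (D(i, f) < d1[i]) g += d1[i] - D(i, f);
    heap.push(Entry(std::make_pair(g, -f), (int)sel.size()));
  }
  while ((int)sel.size() < p && !heap.empty()) {
    Entry top = heap.top(); heap.pop();
    int f = -top.first.second;
    if (inSel[f]) continue;
    if (top.second + stale_tol >= (int)sel.size()) {
      sel.push_back(f); inSel[f] = 1;
      for (int i = 0; i < m; ++i)
        if (D(i, f) < d1[i]) d1[i] = D(i, f);
    } else {
      double g = 0.0;
      for (int i = 0; i < m; ++i)
        if (D(i, f) < d1[i]) g += d1[i] - D(i, f);
      heap.push(Entry(std::make_pair(g, -f), (int)sel.size()));
    }
  }
}

// Pure greedy construction (deterministic, no local search): upper-bound
// reference for the heuristic.
// [[Rcpp::export]]
List cpp_greedy_pmedian(NumericMatrix D, int p) {
  const int n = D.ncol();
  std::vector<int> sel;
  std::vector<char> inSel(n, 0);
  greedy_complete(D, p, sel, inSel);
  std::vector<int> out(sel);
  std::sort(out.begin(), out.end());
  IntegerVector sel1(out.size());
  for (size_t t = 0; t < out.size(); ++t) sel1[t] = out[t] + 1;
  return List::create(_["selected"] = sel1,
                      _["objective"] = obj_from_D(D, sel));
}

// Path relinking: walk from solution a to solution b, at each step applying
// the best (insert from b, drop outside b) swap; returns the best solution
// encountered on the path.
static void path_relink(const NumericMatrix& D, const std::vector<int>& a,
                        const std::vector<int>& b, std::vector<int>& best_sel,
                        double& best_obj) {
  const int m = D.nrow(), n = D.ncol();
  std::vector<char> inCur(n, 0), inB(n, 0);
  std::vector<int> cur(a);
  for (size_t t = 0; t < a.size(); ++t) inCur[a[t]] = 1;
  for (size_t t = 0; t < b.size(); ++t) inB[b[t]] = 1;
  Near nr;
  near_init(D, cur, nr);
  double cur_obj = obj_from_D(D, cur);
  if (cur_obj < best_obj) { best_obj = cur_obj; best_sel = cur; }
  std::vector<double> loss(n, 0.0);
  for (int step = 0; step < (int)a.size() + 1; ++step) {
    // candidate inserts: in b, not in cur; candidate drops: in cur, not in b
    double best_delta = R_PosInf;
    int best_f = -1, best_s = -1;
    for (int f = 0; f < n; ++f) {
      if (!inB[f] || inCur[f]) continue;
      double gain = 0.0;
      for (size_t t = 0; t < cur.size(); ++t) loss[cur[t]] = 0.0;
      for (int i = 0; i < m; ++i) {
        double dif = D(i, f);
        if (dif < nr.d1[i]) gain += nr.d1[i] - dif;
        loss[nr.n1[i]] += std::min(nr.d2[i], dif) - std::min(nr.d1[i], dif);
      }
      for (size_t t = 0; t < cur.size(); ++t) {
        int s = cur[t];
        if (inB[s]) continue;
        double delta = loss[s] - gain;
        if (delta < best_delta) { best_delta = delta; best_f = f; best_s = s; }
      }
    }
    if (best_f < 0) break;
    for (size_t t = 0; t < cur.size(); ++t)
      if (cur[t] == best_s) { cur[t] = best_f; break; }
    inCur[best_s] = 0; inCur[best_f] = 1;
    near_swap(D, cur, best_f, best_s, nr);
    cur_obj += best_delta;
    if (cur_obj < best_obj) {
      best_obj = obj_from_D(D, cur); // exact recompute at improvements
      best_sel = cur;
    }
  }
}

typedef std::pair<double, std::vector<int> > Sol;

// path relinking among the `pool` best distinct local optima, with local
// search on improving relink products; returns the incumbent
static void hybridize_pool(const NumericMatrix& D, const NumericMatrix& Dt,
                           bool fast, std::vector<Sol>& sols, int pool, int p,
                           std::vector<int>& best_sel, double& best_obj) {
  const int n = D.ncol();
  std::sort(sols.begin(), sols.end());
  int P = std::min((int)sols.size(), pool);
  best_sel = sols[0].second;
  best_obj = sols[0].first;
  if (P > 1 && p < n) {
    // relink best with every pool member, plus adjacent pool pairs
    std::vector<std::pair<int, int> > pairs;
    for (int j = 1; j < P; ++j) pairs.push_back(std::make_pair(0, j));
    for (int j = 1; j + 1 < P; ++j) pairs.push_back(std::make_pair(j, j + 1));
    for (size_t q = 0; q < pairs.size(); ++q) {
      std::vector<int> cand = best_sel;
      double cand_obj = best_obj;
      path_relink(D, sols[pairs[q].second].second, sols[pairs[q].first].second,
                  cand, cand_obj);
      if (cand_obj < best_obj) {
        std::vector<char> inSel(n, 0);
        for (size_t t = 0; t < cand.size(); ++t) inSel[cand[t]] = 1;
        double obj = fast ? swap_search_fast(D, Dt, cand, inSel)
                          : swap_search(D, cand, inSel);
        if (obj < best_obj) {
          best_obj = obj;
          best_sel = cand;
        }
      }
    }
  }
  std::sort(best_sel.begin(), best_sel.end());
}

// Multistart heuristic for one or several values of p at once: each start
// builds one randomized lazy-greedy selection up to max(p) (random seed
// site; start 1 is pure greedy) whose nested prefixes seed a
// vertex-substitution local search per p; per p, the best `pool` distinct
// local optima are hybridized by path relinking. Uses the R RNG;
// deterministic under set.seed().
// [[Rcpp::export]]
List cpp_select_pmedian_multi(NumericMatrix D, IntegerVector ps, int n_starts,
                              int pool) {
  const int m = D.nrow(), n = D.ncol();
  const int nq = ps.size();
  const int pmax = Rcpp::max(ps);
  const bool fast = (n <= 2048);
  NumericMatrix Dt;
  if (fast) {
    Dt = NumericMatrix(n, m);
    for (int f = 0; f < n; ++f)
      for (int i = 0; i < m; ++i) Dt(f, i) = D(i, f);
  }
  std::vector<std::vector<Sol> > pools(nq);
  NumericMatrix start_obj(n_starts, nq);
  for (int start = 0; start < n_starts; ++start) {
    std::vector<int> order;
    std::vector<char> inSel(n, 0);
    if (start > 0) {
      int r = (int)std::floor(unif_rand() * n);
      if (r >= n) r = n - 1;
      order.push_back(r); inSel[r] = 1;
    }
    greedy_complete(D, pmax, order, inSel, start == 0 ? 0 : 3);
    for (int q = 0; q < nq; ++q) {
      std::vector<int> sel(order.begin(), order.begin() + ps[q]);
      std::vector<char> in2(n, 0);
      for (size_t t = 0; t < sel.size(); ++t) in2[sel[t]] = 1;
      double obj = fast ? swap_search_fast(D, Dt, sel, in2)
                        : swap_search(D, sel, in2);
      start_obj(start, q) = obj;
      std::sort(sel.begin(), sel.end());
      bool dup = false;
      for (size_t t = 0; t < pools[q].size(); ++t)
        if (pools[q][t].second == sel) { dup = true; break; }
      if (!dup) pools[q].push_back(Sol(obj, sel));
    }
  }
  List out(nq);
  for (int q = 0; q < nq; ++q) {
    std::vector<int> best_sel;
    double best_obj;
    hybridize_pool(D, Dt, fast, pools[q], pool, ps[q], best_sel, best_obj);
    IntegerVector sel1(best_sel.size());
    for (size_t t = 0; t < best_sel.size(); ++t) sel1[t] = best_sel[t] + 1;
    out[q] = List::create(_["selected"] = sel1,
                          _["objective"] = best_obj,
                          _["start_objectives"] = start_obj(_, q));
  }
  return out;
}

// single-p convenience wrapper around the multistart heuristic
// [[Rcpp::export]]
List cpp_select_pmedian(NumericMatrix D, int p, int n_starts, int pool) {
  List r = cpp_select_pmedian_multi(D, IntegerVector::create(p), n_starts,
                                    pool);
  return r[0];
}

// Exhaustive enumeration over all C(n, p) subsets; lexicographic order with
// strict improvement keeps the lexicographically smallest optimum.
// [[Rcpp::export]]
List cpp_pmedian_exact(NumericMatrix D, int p) {
  const int m = D.nrow(), n = D.ncol();
  std::vector<int> c(p);
  for (int t = 0; t < p; ++t) c[t] = t;
  std::vector<int> best(c);
  double best_obj = R_PosInf;
  std::vector<double> dmin(m);
  while (true) {
    double total = 0.0;
    for (int i = 0; i < m; ++i) {
      double b = R_PosInf;
      for (int t = 0; t < p; ++t) {
        double d = D(i, c[t]);
        if (d < b) b = d;
      }
      total += b;
      if (total >= best_obj) {
        // partial sums only grow; cheap early exit
        if (i < m - 1) { total = R_PosInf; }
        break;
      }
    }
    if (total < best_obj) { best_obj = total; best = c; }
    // next combination
    int t = p - 1;
    while (t >= 0 && c[t] == n - p + t) --t;
    if (t < 0) break;
    ++c[t];
    for (int u = t + 1; u < p; ++u) c[u] = c[u - 1] + 1;
  }
  IntegerVector sel1(p);
  for (int t = 0; t < p; ++t) sel1[t] = best[t] + 1;
  return List::create(_["selected"] = sel1, _["objective"] = best_obj);
}
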