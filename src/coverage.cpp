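#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// Cumulative species counts along random site-accumulation orders.
// Returns an n_reps x n_sites matrix: entry (r, p) = number of species
// present in at least one of the first p sites of the r-th random order.
// Uses the R RNG (Fisher-Yates), deterministic under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_random_accum(LogicalMatrix pres, int n_reps) {
  const int n = pres.nrow(), s = pres.ncol();
  // per-species site lists
  std::vector<std::vector<int> > sites(s);
  for (int j = 0; j < s; ++j)
    for (int i = 0; i < n; ++i)
      if (pres(i, j)) sites[j].push_back(i);
  IntegerMatrix out(n_reps, n);
  std::vector<int> perm(n), pos(n), cnt(n + 1);
  for (int r = 0; r < n_reps; ++r) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int k = (int)std::floor(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(perm[i], perm[k]);
    }
    for (int i = 0; i < n; ++i) pos[perm[i]] = i + 1; // 1-based step
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int j = 0; j < s; ++j) {
      if (sites[j].empty()) continue;
      int first = n + 1;
      for (size_t t = 0; t < sites[j].size(); ++t)
        first = std::min(first, pos[sites[j][t]]);
      if (first <= n) cnt[first]++;
    }
    int acc = 0;
    for (int p = 1; p <= n; ++p) {
      acc += cnt[p];
      out(r, p - 1) = acc;
    }
  }
  return out;
}

// Backward core-area removal ranking. Each remaining site i is valued
// v_i = max_j 1/r_j over the species j it holds (r_j = remaining sites
// holding j); the site with the smallest v_i (largest min r_j) is removed,
// ties toward the lowest index. Returns the removal order (1-based) and the
// removal values.
// [[Rcpp::export]]
List cpp_core_removal(LogicalMatrix pres) {
  const int n = pres.nrow(), s = pres.ncol();
  std::vector<std::vector<int> > spp(n); // species per site
  std::vector<int> r(s, 0);
  for (int j = 0; j < s; ++j)
    for (int i = 0; i < n; ++i)
      if (pres(i, j)) { spp[i].push_back(j); ++r[j]; }
  std::vector<char> remaining(n, 1);
  IntegerVector order(n);
  NumericVector values(n);
  const double INF = std::numeric_limits<double>::infinity();
  for (int step = 0; step < n; ++step) {
    int best = -1;
    double best_rmin = -1.0;
    for (int i = 0; i < n; ++i) {
      if (!remaining[i]) continue;
      double rmin = INF; // empty site: v = 0, removed first
      for (size_t t = 0; t < spp[i].size(); ++t)
        if (r[spp[i][t]] < rmin) rmin = r[spp[i][t]];
      if (rmin > best_rmin) { best_rmin = rmin; best = i; }
    }
    order[step] = best + 1;
    values[step] = 1.0 / best_rmin;
    remaining[best] = 0;
    for (size_t t = 0; t < spp[best].size(); ++t) --r[spp[best][t]];
  }
  return List::create(_["order"] = order, _["values"] = values);
}

// Exhaustive maximum coverage: best number of species representable by any
// p sites, via bitset enumeration of all C(n, p) subsets. Lexicographic
// enumeration with strict improvement keeps the lexicographically smallest
// maximizer.
// [[Rcpp::export]]
List cpp_max_coverage_exact(LogicalMatrix pres, int p) {
  const int n = pres.nrow(), s = pres.ncol();
  const int words = (s + 63) / 64;
  std::vector<uint64_t> mask((size_t)n * words, 0u);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < s; ++j)
      if (pres(i, j)) mask[(size_t)i * words + (j >> 6)] |= (uint64_t)1 << (j & 63);
  std::vector<int> c(p);
  for (int t = 0; t < p; ++t) c[t] = t;
  // partial unions per depth
  std::vector<uint64_t> un((size_t)(p + 1) * words, 0u);
  std::vector<int> best(c);
  int best_count = -1;
  int refresh_from = 0;
  while (true) {
    for (int t = refresh_from; t < p; ++t) {
      const uint64_t* prev = &un[(size_t)t * words];
      const uint64_t* mk = &mask[(size_t)c[t] * words];
      uint64_t* curu = &un[(size_t)(t + 1) * words];
      for (int w = 0; w < words; ++w) curu[w] = prev[w] | mk[w];
    }
    int count = 0;
    const uint64_t* full = &un[(size_t)p * words];
    for (int w = 0; w < words; ++w)
      count += __builtin_popcountll(full[w]);
    if (count > best_count) { best_count = count; best = c; }
    int t = p - 1;
    while (t >= 0 && c[t] == n - p + t) --t;
    if (t < 0) break;
    ++c[t];
    for (int u = t + 1; u < p; ++u) c[u] = c[u - 1] + 1;
    refresh_from = t;
  }
  IntegerVector sel1(p);
  for (int t = 0; t < p; ++t) sel1[t] = best[t] + 1;
  return List::create(_["selected"] = sel1, _["coverage"] = best_count);
}
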