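#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Weighted sampling without replacement via exponential keys
// (Efraimidis-Spirakis): taking the mtry smallest keys -log(U)/w_f is
// distributed exactly as sequential draws proportional to the remaining
// weights. Indices are returned in draw order. Entries with w <= 0 are
// never drawn. Consumes R's RNG stream.
static std::vector<int> draw_features_impl(const std::vector<double>& w, int mtry) {
  const int m = (int)w.size();
  std::vector<int> idx;
  idx.reserve(m);
  for (int f = 0; f < m; ++f)
    if (w[f] > 0.0) idx.push_back(f);
  const int npos = (int)idx.size();
  if (mtry > npos) stop("mtry exceeds the number of positive-weight features");
  if (mtry == m && npos == m) {
    // exhaustive draw: every feature is included, no randomness needed
    return idx;
  }
  std::vector<double> key(m, 0.0);
  for (int f : idx) key[f] = -std::log(unif_rand()) / w[f];
  std::nth_element(idx.begin(), idx.begin() + (mtry - 1), idx.end(),
                   [&](int a, int b) { return key[a] < key[b]; });
  idx.resize(mtry);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return key[a] < key[b]; });
  return idx;
}

// [[Rcpp::export]]
IntegerVector cpp_draw_features(NumericVector w, int mtry) {
  std::vector<double> wv(w.begin(), w.end());
  std::vector<int> out = draw_features_impl(wv, mtry);
  return IntegerVector(out.begin(), out.end());
}

struct SplitResult {
  int var = -1;
  double threshold = 0.0;
  double loss = R_PosInf;  // SSE_left + SSE_right = n_L var_L + n_R var_R
};

// Scan one candidate feature over a node's samples given in ascending
// feature order. Thresholds are midpoints between consecutive distinct
// values; both children must hold >= tps samples. Within a feature,
// losses within eps (relative to the node SSE) are treated as tied and
// the lowest threshold is kept; without the tolerance, summation-order
// noise of order 1e-16 would break mathematically exact ties
// arbitrarily. Exact ties are common -- e.g. every split that isolates
// the same single extreme sample has an identical loss.
static void scan_sorted_feature(const double* xcol, const double* y,
                                const int* rows, int n, int f, int tps,
                                double sy, double syy, double eps,
                                SplitResult& best) {
  double sl = 0.0, sql = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double yi = y[rows[i]];
    sl += yi;
    sql += yi * yi;
    const int nl = i + 1, nr = n - nl;
    const double v = xcol[rows[i]], vnext = xcol[rows[i + 1]];
    if (!(vnext > v)) continue;  // not a boundary between distinct values
    if (nl < tps || nr < tps) continue;
    const double sr = sy - sl, sqr = syy - sql;
    double loss = (sql - sl * sl / nl) + (sqr - sr * sr / nr);
    if (loss < 0.0) loss = 0.0;
    if (loss < best.loss - eps) {
      best.loss = loss;
      best.var = f;
      best.threshold = 0.5 * (v + vnext);
    }
  }
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericVector y, IntegerVector rows,
                    IntegerVector candidates, int tps) {
  const int n = rows.size();
  SplitResult best;
  std::vector<int> cand(candidates.begin(), candidates.end());
  std::sort(cand.begin(), cand.end());
  std::vector<int> ord(rows.begin(), rows.end());
  // parent SSE: a split must strictly reduce it
  double sy = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) {
    sy += y[ord[i]];
    syy += y[ord[i]] * y[ord[i]];
  }
  double parent = syy - sy * sy / n;
  if (parent < 0.0) parent = 0.0;
  const double eps = 1e-10 * parent;
  for (int f : cand) {
    const double* xcol = &X(0, f);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return xcol[a] < xcol[b]; });
    scan_sorted_feature(xcol, REAL(y), ord.data(), n, f, tps, sy, syy, eps,
                        best);
  }
  if (best.var < 0 || !(best.loss < parent * (1.0 - 1e-12)))
    return List::create(_["var"] = -1, _["threshold"] = NA_REAL,
                        _["loss"] = NA_REAL);
  return List::create(_["var"] = best.var, _["threshold"] = best.threshold,
                      _["loss"] = best.loss);
}

struct TreeBuilder {
  const NumericMatrix& X;
  const double* y;
  const std::vector<double>& w;
  int mtry, tps, m;
  // ord[f]: the current arrangement of training rows; within any node's
  // segment [lo, hi) every ord[f] holds the same multiset sorted by
  // feature f. buf is scratch for stable partitioning.
  std::vector<std::vector<int>> ord;
  std::vector<int> buf;
  std::vector<int> var, left, right, nsamp;
  std::vector<double> threshold, value;

  TreeBuilder(const NumericMatrix& X_, const double* y_,
              const std::vector<double>& w_, int mtry_, int tps_)
      : X(X_), y(y_), w(w_), mtry(mtry_), tps(tps_), m(X_.ncol()) {}

  int new_node(double mean, int n) {
    var.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    threshold.push_back(NA_REAL);
    value.push_back(mean);
    nsamp.push_back(n);
    return (int)var.size() - 1;
  }

  int build(int lo, int hi) {
    const int n = hi - lo;
    const int* seg0 = ord[0].data() + lo;
    double sy = 0.0, syy = 0.0;
    for (int i = 0; i < n; ++i) {
      const double yi = y[seg0[i]];
      sy += yi;
      syy += yi * yi;
    }
    const int node = new_node(sy / n, n);
    if (n < 2 * tps) return node;
    double parent = syy - sy * sy / n;
    if (parent < 0.0) parent = 0.0;
    if (parent == 0.0) return node;  // constant response

    std::vector<int> cand = draw_features_impl(w, mtry);
    std::sort(cand.begin(), cand.end());
    // Each candidate feature contributes its own best split; features
    // whose optimum ties the global optimum (within eps) are resolved
    // uniformly at random via reservoir sampling from the seeded RNG
    // stream. Deterministic tie resolution would make all trees pick the
    // same split and correlate the ensemble; random resolution matches
    // the reference random-forest behaviour (random candidate order,
    // first best wins) while staying reproducible under the seed.
    SplitResult best;
    const double eps = 1e-10 * parent;
    int n_tied = 0;
    for (int f : cand) {
      const double* xcol = &X(0, f);
      SplitResult local;
      scan_sorted_feature(xcol, y, ord[f].data() + lo, n, f, tps, sy, syy,
                          eps, local);
      if (local.var < 0) continue;
      if (local.loss < best.loss - eps) {
        best = local;
        n_tied = 1;
      } else if (local.loss <= best.loss + eps) {
        n_tied++;
        if (unif_rand() * n_tied < 1.0) {
          const double keep = best.loss;
          best = local;
          if (keep < best.loss) best.loss = keep;  // keep the tightest loss
        }
      }
    }
    if (best.var < 0 || !(best.loss < parent * (1.0 - 1e-12))) return node;

    // stable-partition every feature's segment by the chosen split so each
    // child segment stays sorted per feature
    const double* xsplit = &X(0, best.var);
    int nl = 0;
    for (int f = 0; f < m; ++f) {
      int* seg = ord[f].data() + lo;
      int a = 0, b = 0;
      buf.resize(n);
      for (int i = 0; i < n; ++i) {
        const int r = seg[i];
        if (xsplit[r] <= best.threshold)
          seg[a++] = r;
        else
          buf[b++] = r;
      }
      for (int i = 0; i < b; ++i) seg[a + i] = buf[i];
      nl = a;
    }
    var[node] = best.var;
    threshold[node] = best.threshold;
    const int l = build(lo, lo + nl);
    const int r = build(lo + nl, hi);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

// Fit one CART regression tree on the rows `boot` (0-based, duplicates
// allowed) with per-node weighted feature subsets. `sort_order` holds,
// per feature, the training rows sorted by that feature (0-based); the
// per-tree sorted bootstrap arrays are derived from it by counting, which
// avoids re-sorting every feature for every tree. Uses R's RNG stream.
// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, NumericVector y, IntegerVector boot,
                  IntegerMatrix sort_order, NumericVector w, int mtry,
                  int tps) {
  const int n = boot.size(), m = X.ncol(), ntrain = X.nrow();
  std::vector<double> wv(w.begin(), w.end());
  TreeBuilder tb(X, REAL(y), wv, mtry, tps);
  std::vector<int> count(ntrain, 0);
  for (int i = 0; i < n; ++i) count[boot[i]]++;
  tb.ord.assign(m, std::vector<int>());
  for (int f = 0; f < m; ++f) {
    tb.ord[f].reserve(n);
    const int* so = &sort_order(0, f);
    for (int i = 0; i < ntrain; ++i) {
      const int r = so[i];
      for (int c = 0; c < count[r]; ++c) tb.ord[f].push_back(r);
    }
  }
  tb.build(0, n);
  return List::create(
      _["var"] = IntegerVector(tb.var.begin(), tb.var.end()),
      _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["value"] = NumericVector(tb.value.begin(), tb.value.end()),
      _["nsamp"] = IntegerVector(tb.nsamp.begin(), tb.nsamp.end()));
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(IntegerVector var, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector value, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= threshold[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
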