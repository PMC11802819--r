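#include <Rcpp.h>
#include <random>
#include <stack>
#include <cmath>
using namespace Rcpp;

// Extremely randomized tree: at each node, k candidate features are drawn
// uniformly among the node's non-constant features, one threshold per
// candidate is drawn uniformly in the open (min, max) of that feature over
// the node's rows, candidates are scored by Gini impurity decrease, and the
// best wins (ties -> earliest draw). Pure function of (X, y, params, seed).

namespace {

struct NodeJob {
  std::vector<int> idx;
  int depth;
  int slot;          // index into node arrays
};

inline double gini_from_counts(const std::vector<double>& cnt, double n) {
  double s = 0.0;
  for (double c : cnt) s += (c / n) * (c / n);
  return 1.0 - s;
}

} // namespace

// [[Rcpp::export(name = ".et_fit_cpp")]]
List et_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                int k_features, int min_samples_split, int max_depth,
                double seed) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 1) stop("empty training set");
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  std::vector<int> feat;            // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;     // 0-based node indices, -1 for leaf
  std::vector<std::vector<double>> counts;

  std::vector<int> featpool(d);

  std::stack<NodeJob> jobs;
  {
    NodeJob root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    root.depth = 0;
    root.slot = 0;
    feat.push_back(-1); thr.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1);
    counts.push_back(std::vector<double>(n_classes, 0.0));
    jobs.push(std::move(root));
  }

  while (!jobs.empty()) {
    NodeJob job = std::move(jobs.top());
    jobs.pop();
    const std::vector<int>& idx = job.idx;
    const int nn = (int)idx.size();

    std::vector<double> cnt(n_classes, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    counts[job.slot] = cnt;

    int nz = 0;
    for (double c : cnt) if (c > 0) ++nz;
    bool leaf = (nz <= 1) || (nn < min_samples_split) ||
                (max_depth >= 0 && job.depth >= max_depth);

    int best_f = -1;
    double best_thr = 0.0, best_gain = -1.0;

    if (!leaf) {
      const double imp_parent = gini_from_counts(cnt, (double)nn);
      // Fisher-Yates walk over the feature pool; constants are rejected so
      // accepted candidates are uniform among the node's non-constant features.
      for (int f = 0; f < d; ++f) featpool[f] = f;
      int accepted = 0;
      for (int t = 0; t < d && accepted < k_features; ++t) {
        std::uniform_int_distribution<int> pick(t, d - 1);
        int j = pick(rng);
        std::swap(featpool[t], featpool[j]);
        const int f = featpool[t];
        double mn = X(idx[0], f), mx = mn;
        for (int i = 1; i < nn; ++i) {
          double v = X(idx[i], f);
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
        if (!(mx > mn)) continue;      // constant at this node
        double u = unif01(rng);
        double cand = mn + u * (mx - mn);
        if (cand <= mn) cand = std::nextafter(mn, mx);
        ++accepted;
        std::vector<double> cl(n_classes, 0.0);
        double nl = 0.0;
        for (int i : idx) {
          if (X(i, f) < cand) { cl[y[i]] += 1.0; nl += 1.0; }
        }
        double nr = (double)nn - nl;
        if (nl == 0.0 || nr == 0.0) continue;   // cannot happen, but guard
        std::vector<double> cr(n_classes);
        for (int k = 0; k < n_classes; ++k) cr[k] = cnt[k] - cl[k];
        double gain = imp_parent
          - (nl / nn) * gini_from_counts(cl, nl)
          - (nr / nn) * gini_from_counts(cr, nr);
        if (gain > best_gain) {        // strict: ties keep earliest candidate
          best_gain = gain; best_f = f; best_thr = cand;
        }
      }
      if (best_f < 0) leaf = true;     // all features constant at this node
    }

    if (leaf) continue;                // counts already stored

    NodeJob lj, rj;
    for (int i : idx) {
      if (X(i, best_f) < best_thr) lj.idx.push_back(i);
      else rj.idx.push_back(i);
    }
    feat[job.slot] = best_f;
    thr[job.slot] = best_thr;

    lj.depth = rj.depth = job.depth + 1;
    lj.slot = (int)feat.size();
    feat.push_back(-1); thr.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1);
    counts.push_back(std::vector<double>(n_classes, 0.0));
    rj.slot = (int)feat.size();
    feat.push_back(-1); thr.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1);
    counts.push_back(std::vector<double>(n_classes, 0.0));
    left[job.slot] = lj.slot;
    right[job.slot] = rj.slot;
    jobs.push(std::move(rj));          // LIFO: left child processed first
    jobs.push(std::move(lj));
  }

  const int m = (int)feat.size();
  NumericMatrix cm(m, n_classes);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < n_classes; ++k) cm(i, k) = counts[i][k];
  return List::create(_["feature"] = IntegerVector(feat.begin(), feat.end()),
                      _["threshold"] = NumericVector(thr.begin(), thr.end()),
                      _["left"] = IntegerVector(left.begin(), left.end()),
                      _["right"] = IntegerVector(right.begin(), right.end()),
                      _["counts"] = cm);
}

// [[Rcpp::export(name = ".et_predict_cpp")]]
List et_predict_cpp(IntegerVector feature, NumericVector threshold,
                    IntegerVector left, IntegerVector right,
                    NumericMatrix counts, NumericMatrix X) {
  const int n = X.nrow(), K = counts.ncol();
  IntegerVector lab(n);
  NumericMatrix prob(n, K);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) < threshold[node]) ? left[node] : right[node];
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += counts(node, k);
    int arg = 0; double best = -1.0;
    for (int k = 0; k < K; ++k) {
      prob(i, k) = counts(node, k) / tot;
      if (counts(node, k) > best) { best = counts(node, k); arg = k; }
    }
    lab[i] = arg;                      // ties -> lowest class index
  }
  return List::create(_["labels"] = lab, _["prob"] = prob);
}

// Zero-phase IIR filtering of matrix columns: odd (reflected) padding of
// 3 * (nfilt - 1) samples at both ends, forward pass, backward pass.
// [[Rcpp::export(name = ".filtfilt_mat_cpp")]]
NumericMatrix filtfilt_mat_cpp(NumericVector b, NumericVector a,
                               NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  const int nb = b.size(), na = a.size();
  const int nfilt = std::max(nb, na);
  const int pad = 3 * (nfilt - 1);
  if (n <= pad) stop("signal too short for the filter's padding");
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];

  NumericMatrix out(n, m);
  const int N = n + 2 * pad;
  std::vector<double> x(N), yv(N);

  for (int c = 0; c < m; ++c) {
    for (int i = 0; i < pad; ++i) x[i] = 2.0 * X(0, c) - X(pad - i, c);
    for (int i = 0; i < n; ++i) x[pad + i] = X(i, c);
    for (int i = 0; i < pad; ++i)
      x[pad + n + i] = 2.0 * X(n - 1, c) - X(n - 2 - i, c);

    // forward, direct form I with zero initial state
    for (int t = 0; t < N; ++t) {
      double acc = 0.0;
      for (int i = 0; i < nfilt && i <= t; ++i) acc += bb[i] * x[t - i];
      for (int i = 1; i < nfilt && i <= t; ++i) acc -= aa[i] * yv[t - i];
      yv[t] = acc;
    }
    std::reverse(yv.begin(), yv.end());
    std::swap(x, yv);
    for (int t = 0; t < N; ++t) {
      double acc = 0.0;
      for (int i = 0; i < nfilt && i <= t; ++i) acc += bb[i] * x[t - i];
      for (int i = 1; i < nfilt && i <= t; ++i) acc -= aa[i] * yv[t - i];
      yv[t] = acc;
    }
    std::reverse(yv.begin(), yv.end());
    for (int i = 0; i < n; ++i) out(i, c) = yv[pad + i];
  }
  return out;
}
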