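#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted Gini decision tree, the base learner for the boosting module.
//
// Exhaustive axis-aligned split search with deterministic tie-breaking:
// features are scanned in ascending index order and candidate thresholds in
// ascending value order, and a split replaces the incumbent only on a strict
// improvement (> 1e-12), so the lowest feature index / lowest threshold wins.
// Thresholds are midpoints between consecutive distinct values; x <= thr
// routes left. Leaves predict the class of largest weighted mass (ties: the
// lowest class index, i.e. first in class_set order).

struct TreeBuild {
  const NumericMatrix& X;
  const IntegerVector& y;   // 0-based class codes
  const NumericVector& w;
  int k, maxDepth;
  std::vector<int> feature, left, right, pred;
  std::vector<double> threshold;

  TreeBuild(const NumericMatrix& X_, const IntegerVector& y_,
            const NumericVector& w_, int k_, int maxDepth_)
    : X(X_), y(y_), w(w_), k(k_), maxDepth(maxDepth_) {}

  static double giniSum(const std::vector<double>& cnt, double tot) {
    if (tot <= 0) return 0.0;
    double s = 0.0;
    for (double c : cnt) s += c * c;
    return tot - s / tot;  // tot * Gini impurity
  }

  int majority(const std::vector<double>& cnt) {
    int best = 0;
    for (int c = 1; c < k; ++c) if (cnt[c] > cnt[best]) best = c;
    return best;
  }

  int build(std::vector<int>& idx, int depth) {
    int node = (int)feature.size();
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0);

    std::vector<double> cnt(k, 0.0);
    double tot = 0.0;
    for (int i : idx) { cnt[y[i]] += w[i]; tot += w[i]; }
    pred[node] = majority(cnt);

    double parentImp = giniSum(cnt, tot);
    if (depth >= maxDepth || parentImp <= 1e-12 || idx.size() < 2) return node;

    int p = X.ncol();
    int bestFeat = -1;
    double bestThr = 0.0, bestGain = 1e-12;

    std::vector<int> ord(idx);
    std::vector<double> cl(k);
    for (int j = 0; j < p; ++j) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, j), xb = X(b, j);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      std::fill(cl.begin(), cl.end(), 0.0);
      double wl = 0.0;
      for (size_t r = 0; r + 1 < ord.size(); ++r) {
        int i = ord[r];
        cl[y[i]] += w[i];
        wl += w[i];
        double xcur = X(i, j), xnext = X(ord[r + 1], j);
        if (xcur == xnext) continue;
        // right-side counts by difference
        double wr = tot - wl, childImp = giniSum(cl, wl);
        double sR = 0.0;
        for (int c = 0; c < k; ++c) {
          double rc = cnt[c] - cl[c];
          sR += rc * rc;
        }
        childImp += (wr <= 0 ? 0.0 : wr - sR / wr);
        double gain = parentImp - childImp;
        if (gain > bestGain) {
          bestGain = gain;
          bestFeat = j;
          bestThr = xcur + (xnext - xcur) / 2.0;
        }
      }
    }
    if (bestFeat < 0) return node;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, bestFeat) <= bestThr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    feature[node] = bestFeat;
    threshold[node] = bestThr;
    left[node] = build(li, depth + 1);
    right[node] = build(ri, depth + 1);
    return node;
  }
};

// [[Rcpp::export]]
List fitTreeCpp(NumericMatrix X, IntegerVector y, NumericVector w, int k, int maxDepth) {
  TreeBuild tb(X, y, w, k, maxDepth);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  tb.build(idx, 0);
  return List::create(
    _["feature"] = wrap(tb.feature),
    _["threshold"] = wrap(tb.threshold),
    _["left"] = wrap(tb.left),
    _["right"] = wrap(tb.right),
    _["pred"] = wrap(tb.pred));
}

// [[Rcpp::export]]
IntegerVector predictTreeCpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector threshold = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
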