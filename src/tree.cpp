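#include <Rcpp.h>
using namespace Rcpp;

// Classification tree with Gini splits, used both for CART (mtry = d, no
// bootstrap) and as the base learner of the random forest (mtry < d,
// bootstrap indices supplied by the caller). Feature subsampling draws from
// R's RNG so a set.seed() on the R side makes forests reproducible.

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, mtry, d, min_n;
  std::vector<int> feature, left, right, pred;
  std::vector<double> threshold;
  std::vector<double> importance; // unnormalized sum of impurity decreases

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K_, int mtry_,
              int min_n_)
      : X(X_), y(y_), K(K_), mtry(mtry_), d(X_.ncol()), min_n(min_n_),
        importance(X_.ncol(), 0.0) {}

  static double gini(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double g = 1.0;
    for (int c : cnt) {
      const double p = (double)c / n;
      g -= p * p;
    }
    return g;
  }

  int majority(const std::vector<int>& cnt) {
    int best = 0;
    for (int k = 1; k < K; ++k)
      if (cnt[k] > cnt[best]) best = k; // ties -> smaller class index
    return best;
  }

  // grow node over sample indices idx (rows of X, 0-based); returns node id
  int grow(std::vector<int>& idx) {
    const int n = (int)idx.size();
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    const double g0 = gini(cnt, n);
    const int id = (int)feature.size();
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(majority(cnt));
    if (n < min_n || g0 <= 0.0) return id;

    // sample mtry features without replacement (R RNG)
    std::vector<int> feats(d);
    for (int j = 0; j < d; ++j) feats[j] = j;
    if (mtry < d) {
      for (int j = 0; j < mtry; ++j) {
        int pick = j + (int)std::floor(unif_rand() * (d - j));
        if (pick >= d) pick = d - 1;
        std::swap(feats[j], feats[pick]);
      }
    }
    const int nf = std::min(mtry, d);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> cl(K), cr(K);
    for (int jj = 0; jj < nf; ++jj) {
      const int f = feats[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      std::fill(cl.begin(), cl.end(), 0);
      cr = cnt;
      for (int i = 0; i < n - 1; ++i) {
        cl[vals[i].second]++;
        cr[vals[i].second]--;
        if (vals[i + 1].first <= vals[i].first) continue; // tied values
        const int nl = i + 1, nr = n - nl;
        const double gain =
            g0 - ((double)nl / n) * gini(cl, nl) - ((double)nr / n) * gini(cr, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return id;
    importance[best_f] += n * best_gain;
    feature[id] = best_f;
    threshold[id] = best_thr;
    const int l = grow(li);
    left[id] = l;
    const int r = grow(ri);
    right[id] = r;
    return id;
  }
};

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, int K, int mtry,
                   IntegerVector sample_idx, int min_n) {
  TreeBuilder tb(X, y, K, mtry, min_n);
  std::vector<int> idx(sample_idx.begin(), sample_idx.end());
  tb.grow(idx);
  return List::create(_["feature"] = wrap(tb.feature),
                      _["threshold"] = wrap(tb.threshold),
                      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
                      _["pred"] = wrap(tb.pred),
                      _["importance"] = wrap(tb.importance));
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               IntegerVector pred, NumericMatrix X) {
  const int n = X.nrow();
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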