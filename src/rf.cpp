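#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Random forest for imputation: bootstrap + random feature subsets, CART
// trees grown with histogram split search. Each feature is pre-binned into
// at most 64 quantile bins (binary dummies and small ordinal codes keep
// their exact values), so a node/feature scan is one pass over the node's
// rows plus a sweep over the bins. Variance criterion for regression, Gini
// for classification; categorical predictors arrive dummy-coded. Uses R's
// RNG, so results are reproducible under set.seed().

namespace {

const int MAX_BINS = 64;

inline int runif_int(int n) {  // uniform on 0..n-1
  int v = (int)(R::unif_rand() * n);
  return v >= n ? n - 1 : v;
}

struct BinnedFeature {
  std::vector<double> thr;        // split thresholds between bins (size nbins-1)
  std::vector<uint8_t> code;      // per training row, bin index
  int nbins;
};

void bin_feature(const double* x, int n, BinnedFeature& bf) {
  std::vector<double> v(x, x + n);
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  const int nu = (int)v.size();
  if (nu <= MAX_BINS) {
    bf.thr.resize(nu > 1 ? nu - 1 : 0);
    for (int i = 0; i + 1 < nu; ++i) bf.thr[i] = 0.5 * (v[i] + v[i + 1]);
  } else {
    bf.thr.clear();
    for (int b = 1; b < MAX_BINS; ++b) {
      double q = v[(size_t)((double)b / MAX_BINS * (nu - 1))];
      if (bf.thr.empty() || q > bf.thr.back()) bf.thr.push_back(q);
    }
  }
  bf.nbins = (int)bf.thr.size() + 1;
  bf.code.resize(n);
  for (int i = 0; i < n; ++i) {
    bf.code[i] = (uint8_t)(std::upper_bound(bf.thr.begin(), bf.thr.end(), x[i])
                           - bf.thr.begin());
  }
}

struct Tree {
  std::vector<int> feat;          // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> pred;
};

struct Job { int node, lo, hi, depth; };

class Builder {
public:
  Builder(const std::vector<BinnedFeature>& bins, const double* y,
          int mtry, int min_leaf, int max_depth, bool classif, int n_classes)
    : bins_(bins), y_(y), mtry_(mtry), min_leaf_(min_leaf),
      max_depth_(max_depth), classif_(classif), K_(std::max(n_classes, 1)),
      p_((int)bins.size()), feats_(p_),
      cnt_(MAX_BINS * K_), sum_(MAX_BINS), accL_(K_), tot_(K_) {
    for (int j = 0; j < p_; ++j) feats_[j] = j;
  }

  void build(Tree& tr, std::vector<int>& rows) {
    tr.feat.assign(1, -1); tr.thr.assign(1, 0.0);
    tr.left.assign(1, -1); tr.right.assign(1, -1); tr.pred.assign(1, 0.0);
    std::vector<Job> stack;
    stack.push_back(Job{0, 0, (int)rows.size(), 0});
    while (!stack.empty()) {
      Job jb = stack.back(); stack.pop_back();
      grow(tr, rows, jb, stack);
    }
  }

private:
  void leaf(Tree& tr, const std::vector<int>& rows, const Job& jb) {
    if (!classif_) {
      double s = 0.0;
      for (int m = jb.lo; m < jb.hi; ++m) s += y_[rows[m]];
      tr.pred[jb.node] = s / (jb.hi - jb.lo);
    } else {
      std::vector<double> ct(K_, 0.0);
      for (int m = jb.lo; m < jb.hi; ++m) ct[(int)y_[rows[m]]] += 1.0;
      int best = 0;
      for (int c = 1; c < K_; ++c) if (ct[c] > ct[best]) best = c;
      tr.pred[jb.node] = best;
    }
  }

  void grow(Tree& tr, std::vector<int>& rows, const Job& jb,
            std::vector<Job>& stack) {
    const int n = jb.hi - jb.lo;
    bool pure = true;
    for (int m = jb.lo + 1; m < jb.hi; ++m) {
      if (y_[rows[m]] != y_[rows[jb.lo]]) { pure = false; break; }
    }
    if (n < 2 * min_leaf_ || pure || jb.depth >= max_depth_) {
      leaf(tr, rows, jb); return;
    }

    for (int m = 0; m < mtry_; ++m) {          // mtry distinct features
      int r = m + runif_int(p_ - m);
      std::swap(feats_[m], feats_[r]);
    }

    int best_f = -1, best_s = -1; double best_score = -1e300;
    for (int fm = 0; fm < mtry_; ++fm) {
      const int f = feats_[fm];
      const BinnedFeature& bf = bins_[f];
      if (bf.nbins < 2) continue;
      const int nb = bf.nbins;
      if (classif_) {
        std::fill(cnt_.begin(), cnt_.begin() + nb * K_, 0.0);
        for (int m = jb.lo; m < jb.hi; ++m) {
          int r = rows[m];
          cnt_[bf.code[r] * K_ + (int)y_[r]] += 1.0;
        }
        std::vector<double>& accL = accL_; std::vector<double>& tot = tot_;
        std::fill(accL.begin(), accL.end(), 0.0);
        std::fill(tot.begin(), tot.end(), 0.0);
        double nT = n;
        for (int b = 0; b < nb; ++b)
          for (int c = 0; c < K_; ++c) tot[c] += cnt_[b * K_ + c];
        double nL = 0.0;
        for (int s = 0; s < nb - 1; ++s) {
          for (int c = 0; c < K_; ++c) {
            accL[c] += cnt_[s * K_ + c];
            nL += cnt_[s * K_ + c];
          }
          double nR = nT - nL;
          if (nL < min_leaf_ || nR < min_leaf_) continue;
          double s2L = 0.0, s2R = 0.0;
          for (int c = 0; c < K_; ++c) {
            s2L += accL[c] * accL[c];
            double rr = tot[c] - accL[c];
            s2R += rr * rr;
          }
          double score = s2L / nL + s2R / nR;
          if (score > best_score) { best_score = score; best_f = f; best_s = s; }
        }
      } else {
        std::fill(sum_.begin(), sum_.begin() + nb, 0.0);
        std::fill(cnt_.begin(), cnt_.begin() + nb, 0.0);
        for (int m = jb.lo; m < jb.hi; ++m) {
          int r = rows[m];
          sum_[bf.code[r]] += y_[r];
          cnt_[bf.code[r]] += 1.0;
        }
        double sT = 0.0;
        for (int b = 0; b < nb; ++b) sT += sum_[b];
        double sL = 0.0, nL = 0.0;
        for (int s = 0; s < nb - 1; ++s) {
          sL += sum_[s]; nL += cnt_[s];
          double nR = n - nL;
          if (nL < min_leaf_ || nR < min_leaf_) continue;
          double sR = sT - sL;
          double score = sL * sL / nL + sR * sR / nR;
          if (score > best_score) { best_score = score; best_f = f; best_s = s; }
        }
      }
    }

    if (best_f < 0) { leaf(tr, rows, jb); return; }

    const BinnedFeature& bf = bins_[best_f];
    const uint8_t cut = (uint8_t)best_s;
    std::vector<int>::iterator first = rows.begin() + jb.lo,
                               last = rows.begin() + jb.hi;
    std::vector<int>::iterator mid = std::partition(
        first, last, [&](int r) { return bf.code[r] <= cut; });
    int nL = (int)(mid - first);
    if (nL < min_leaf_ || (jb.hi - jb.lo - nL) < min_leaf_) {
      leaf(tr, rows, jb); return;
    }

    int ln = (int)tr.feat.size(), rn = ln + 1;
    tr.feat[jb.node] = best_f;
    tr.thr[jb.node] = bf.thr[best_s];
    tr.left[jb.node] = ln; tr.right[jb.node] = rn;
    for (int t = 0; t < 2; ++t) {
      tr.feat.push_back(-1); tr.thr.push_back(0.0);
      tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(0.0);
    }
    stack.push_back(Job{ln, jb.lo, jb.lo + nL, jb.depth + 1});
    stack.push_back(Job{rn, jb.lo + nL, jb.hi, jb.depth + 1});
  }

  const std::vector<BinnedFeature>& bins_;
  const double* y_;
  int mtry_, min_leaf_, max_depth_;
  bool classif_;
  int K_, p_;
  std::vector<int> feats_;
  std::vector<double> cnt_, sum_, accL_, tot_;
};

inline double predict_one(const Tree& tr, const double* xrow) {
  int node = 0;
  while (tr.feat[node] >= 0) {
    node = (xrow[tr.feat[node]] <= tr.thr[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

}  // namespace

// Fit a forest on (Xtr, y) and predict Xte. For classification y holds
// class codes 0..n_classes-1 and majority-vote codes are returned (vote
// ties towards the smaller code); for regression the mean over trees.
// [[Rcpp::export]]
NumericVector rf_fit_predict_cpp(NumericMatrix Xtr, NumericVector y,
                                 NumericMatrix Xte, int n_trees, int mtry,
                                 int min_leaf, int max_depth,
                                 bool classification, int n_classes) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), nte = Xte.nrow();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (n < 1) stop("empty training set");

  std::vector<BinnedFeature> bins(p);
  std::vector<double> col(n);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) col[i] = Xtr(i, f);
    bin_feature(col.data(), n, bins[f]);
  }
  std::vector<double> yv(y.begin(), y.end());

  // row-major copy of the test matrix for cache-friendly prediction
  std::vector<double> te((size_t)nte * p);
  for (int i = 0; i < nte; ++i)
    for (int f = 0; f < p; ++f) te[(size_t)i * p + f] = Xte(i, f);

  NumericVector out(nte);
  std::vector<std::vector<double> > votes;
  if (classification)
    votes.assign(nte, std::vector<double>(n_classes, 0.0));

  Builder builder(bins, yv.data(), mtry, min_leaf, max_depth,
                  classification, n_classes);
  std::vector<int> boot(n);
  Tree tr;
  for (int t = 0; t < n_trees; ++t) {
    for (int m = 0; m < n; ++m) boot[m] = runif_int(n);
    builder.build(tr, boot);
    for (int r = 0; r < nte; ++r) {
      double pr = predict_one(tr, &te[(size_t)r * p]);
      if (classification) votes[r][(int)pr] += 1.0;
      else out[r] += pr;
    }
  }
  if (classification) {
    for (int r = 0; r < nte; ++r) {
      int best = 0;
      for (int c = 1; c < n_classes; ++c)
        if (votes[r][c] > votes[r][best]) best = c;
      out[r] = best;
    }
  } else {
    for (int r = 0; r < nte; ++r) out[r] /= n_trees;
  }
  return out;
}
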