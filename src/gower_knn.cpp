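#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Gower k-nearest-neighbour imputation for mixed-type rows.
//
// X:        n x p matrix; categorical variables coded 1..K, NA = missing.
//           At most one missing cell per row is assumed (enforced upstream
//           by the amputation design); rows violating this are rejected.
// dist_cat: per column, TRUE -> 0/1 mismatch distance, FALSE -> |a-b|/range
//           (ordinal variables enter as level codes with their rank range,
//           equal to the rank-scaled-to-[0,1] convention).
// ranges:   per column, the denominator for numeric distance (> 0).
// agg_cat:  per column, TRUE -> fill with donor mode (ties -> smallest
//           code), FALSE -> donor median.
// case_id:  distance ties broken towards the smaller case id.
//
// Distance between two rows averages over the columns observed in both,
// excluding the target column. Categorical columns are packed one byte
// each into a 64-bit word per row, so the mismatch count of a row pair is
// an XOR plus a per-byte nonzero fold; numeric columns are pre-scaled by
// 1/range and accumulated directly.

namespace {

const uint64_t LSB_MASK = 0x0101010101010101ULL;

// per-byte nonzero -> count of mismatching packed columns
inline int byte_mismatch_count(uint64_t y) {
  uint64_t t = y;
  t |= t >> 1;
  t |= t >> 2;
  t |= t >> 4;
  return __builtin_popcountll(t & LSB_MASK);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix gower_knn_impute_cpp(NumericMatrix X, LogicalVector dist_cat,
                                   NumericVector ranges, LogicalVector agg_cat,
                                   IntegerVector case_id, int k) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out = clone(X);

  // column layout: categorical columns get a byte slot, numeric columns a
  // pre-scaled value array
  std::vector<int> cat_slot(p, -1), num_slot(p, -1);
  std::vector<int> cat_cols, num_cols;
  for (int j = 0; j < p; ++j) {
    if (dist_cat[j]) { cat_slot[j] = (int)cat_cols.size(); cat_cols.push_back(j); }
    else             { num_slot[j] = (int)num_cols.size(); num_cols.push_back(j); }
  }
  if ((int)cat_cols.size() > 8)
    stop("at most 8 categorical columns supported by the packed kernel");

  std::vector<uint64_t> packed(n, 0);
  std::vector<std::vector<double> > num(num_cols.size(),
                                        std::vector<double>(n, 0.0));
  std::vector<int> miss_col(n, -1);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) {
      double v = X(i, j);
      if (NumericMatrix::is_na(v)) {
        if (miss_col[i] >= 0)
          stop("row %d has more than one missing cell", i + 1);
        miss_col[i] = j;       // packed byte / numeric value stays 0
      } else if (cat_slot[j] >= 0) {
        packed[i] |= ((uint64_t)(uint8_t)v) << (8 * cat_slot[j]);
      } else {
        num[num_slot[j]][i] = v / ranges[j];
      }
    }
  }

  std::vector<double> bd(k);
  std::vector<int> bi(k);
  std::vector<double> vals(k);

  for (int i = 0; i < n; ++i) {
    const int j = miss_col[i];
    if (j < 0) continue;

    // target-specific exclusions
    uint64_t mask = ~0ULL;
    if (cat_slot[j] >= 0) mask &= ~(0xFFULL << (8 * cat_slot[j]));
    std::vector<int> num_active;
    for (size_t m = 0; m < num_cols.size(); ++m)
      if (num_cols[m] != j) num_active.push_back((int)m);
    const int used_base = p - 1;
    const uint64_t wi = packed[i];

    int nbest = 0;
    for (int r = 0; r < n; ++r) {
      if (r == i || miss_col[r] == j) continue;  // donor must observe j
      double acc = (double)byte_mismatch_count((wi ^ packed[r]) & mask);
      for (size_t m = 0; m < num_active.size(); ++m) {
        const std::vector<double>& col = num[num_active[m]];
        acc += std::fabs(col[i] - col[r]);
      }
      int used = used_base;
      const int mc = miss_col[r];
      if (mc >= 0) {                 // donor misses some other column
        if (cat_slot[mc] >= 0) {
          acc -= 1.0;                // its zero byte always mismatches
        } else {
          acc -= std::fabs(num[num_slot[mc]][i]);  // donor value stored 0
        }
        --used;
      }
      if (used == 0) continue;
      double d = acc / used;
      if (nbest == k && d > bd[k - 1]) continue;
      int pos = nbest;
      while (pos > 0 &&
             (d < bd[pos - 1] ||
              (d == bd[pos - 1] && case_id[r] < case_id[bi[pos - 1]]))) {
        --pos;
      }
      if (pos < k) {
        int last = std::min(nbest, k - 1);
        for (int m = last; m > pos; --m) { bd[m] = bd[m - 1]; bi[m] = bi[m - 1]; }
        bd[pos] = d; bi[pos] = r;
        if (nbest < k) ++nbest;
      }
    }
    if (nbest == 0) stop("no eligible donor for a missing cell");
    for (int m = 0; m < nbest; ++m) vals[m] = X(bi[m], j);
    std::sort(vals.begin(), vals.begin() + nbest);
    if (agg_cat[j]) {
      // mode over donors; ties towards the smallest level code
      double best_val = vals[0]; int best_ct = 1, ct = 1;
      for (int m = 1; m < nbest; ++m) {
        if (vals[m] == vals[m - 1]) ++ct; else ct = 1;
        if (ct > best_ct) { best_ct = ct; best_val = vals[m]; }
      }
      out(i, j) = best_val;
    } else {
      out(i, j) = (nbest % 2 == 1)
        ? vals[nbest / 2]
        : 0.5 * (vals[nbest / 2 - 1] + vals[nbest / 2]);
    }
  }
  return out;
}
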