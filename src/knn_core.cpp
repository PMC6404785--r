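#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Squared Euclidean distance between row i of A and row j of B over the
// (0-based) feature columns in `cols`.
static inline double sqdist_cols(const NumericMatrix &A, int i,
                                 const NumericMatrix &B, int j,
                                 const std::vector<int> &cols) {
  double s = 0.0;
  for (size_t f = 0; f < cols.size(); ++f) {
    double d = A(i, cols[f]) - B(j, cols[f]);
    s += d * d;
  }
  return s;
}

// Ordering used throughout: ascending distance, exact distance ties
// resolved to the lowest training index. Comparing (distance, index)
// pairs makes this a strict weak ordering, so partial selection gives the
// same head of the order as a full stable sort.
struct DistCmp {
  const std::vector<double> &d;
  explicit DistCmp(const std::vector<double> &d_) : d(d_) {}
  bool operator()(int a, int b) const {
    return d[a] < d[b] || (d[a] == d[b] && a < b);
  }
};

static inline void stable_order(const std::vector<double> &d,
                                std::vector<int> &idx) {
  int n = (int)d.size();
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), DistCmp(d));
}

// Order only the first `top` ranks (rest of idx unspecified); falls back
// to a full sort when top >= n.
static inline void partial_order(const std::vector<double> &d, int top,
                                 std::vector<int> &idx) {
  int n = (int)d.size();
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  if (top >= n) {
    std::sort(idx.begin(), idx.end(), DistCmp(d));
  } else {
    std::partial_sort(idx.begin(), idx.begin() + top, idx.end(), DistCmp(d));
  }
}

// Class-1 probability from a sorted neighbour order with per-point
// multiplicities w (bootstrap counts; pass all ones for plain kNN).
static inline double prob_from_order(const std::vector<int> &idx, int upto,
                                     const IntegerVector &y,
                                     const int *w, int k, int *taken_out) {
  int taken = 0;
  double s1 = 0.0;
  for (int r = 0; r < upto && taken < k; ++r) {
    int i = idx[r];
    int wi = w ? w[i] : 1;
    if (wi <= 0) continue;
    int take = std::min(wi, k - taken);
    s1 += (double)take * (double)y[i];
    taken += take;
  }
  if (taken_out) *taken_out = taken;
  return s1 / (double)k;
}

// Weighted kNN probability using partial selection first; widens to a
// full sort in the (rare) case the ordered prefix does not yet carry k
// units of bootstrap weight.
static inline double knn_prob_weighted(const std::vector<double> &d,
                                       const IntegerVector &y, const int *w,
                                       int k, std::vector<int> &idx) {
  int n = (int)d.size();
  int top = w ? std::min(n, 4 * k + 64) : std::min(n, k);
  partial_order(d, top, idx);
  int taken = 0;
  double p = prob_from_order(idx, top, y, w, k, &taken);
  if (taken < k && top < n) {
    stable_order(d, idx);
    p = prob_from_order(idx, n, y, w, k, NULL);
  }
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_dist(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("column counts differ");
  NumericMatrix D(na, nb);
  for (int j = 0; j < nb; ++j) {
    for (int i = 0; i < na; ++i) {
      double s = 0.0;
      for (int f = 0; f < d; ++f) {
        double t = A(i, f) - B(j, f);
        s += t * t;
      }
      D(i, j) = std::sqrt(s);
    }
  }
  return D;
}

// Class-1 probabilities for each query and each k in `ks` (unit weights).
// One distance pass and one stable sort per query, shared across all k.
// [[Rcpp::export]]
NumericMatrix cpp_knn_prob_multik(NumericMatrix train, IntegerVector y,
                                  NumericMatrix query, IntegerVector ks) {
  int n = train.nrow(), nq = query.nrow(), nk = ks.size();
  std::vector<int> cols(train.ncol());
  for (int f = 0; f < (int)cols.size(); ++f) cols[f] = f;
  NumericMatrix P(nq, nk);
  std::vector<double> d(n);
  std::vector<int> idx;
  int kmax = 0;
  for (int j = 0; j < nk; ++j) kmax = std::max(kmax, (int)ks[j]);
  for (int q = 0; q < nq; ++q) {
    for (int i = 0; i < n; ++i) d[i] = sqdist_cols(query, q, train, i, cols);
    partial_order(d, std::min(n, kmax), idx);
    // cumulative class-1 counts along the sorted order
    double cum = 0.0;
    int pos = 0;
    for (int j = 0; j < nk; ++j) {
      int k = ks[j];
      while (pos < k && pos < n) cum += (double)y[idx[pos++]];
      P(q, j) = cum / (double)k;
    }
  }
  return P;
}

// Per-member class-1 probabilities for an ensemble of subset-kNN models.
// subsets: list of 1-based feature index vectors, one per member.
// W: B x n bootstrap count matrix, or a 0-row matrix for unit weights
// (all training points in every member, as in random-subspace ensembles).
// [[Rcpp::export]]
NumericMatrix cpp_members_subset(NumericMatrix train, IntegerVector y,
                                 NumericMatrix query, List subsets,
                                 IntegerMatrix W, int k) {
  int n = train.nrow(), nq = query.nrow(), B = subsets.size();
  bool weighted = W.nrow() > 0;
  if (weighted && (W.nrow() != B || W.ncol() != n))
    stop("weight matrix must be B x n");
  NumericMatrix P(B, nq);
  std::vector<int> idx;
  for (int b = 0; b < B; ++b) {
    IntegerVector sub = subsets[b];
    std::vector<int> cols(sub.size());
    for (int f = 0; f < (int)cols.size(); ++f) cols[f] = sub[f] - 1;
    // compact the member's training set to its in-bag rows (ascending
    // original index, so the lowest-index tie rule is preserved)
    std::vector<int> act;
    std::vector<int> actw;
    IntegerVector acty(n);
    int na = 0;
    if (weighted) {
      for (int i = 0; i < n; ++i)
        if (W(b, i) > 0) {
          act.push_back(i);
          actw.push_back(W(b, i));
          acty[na++] = y[i];
        }
    } else {
      na = n;
      for (int i = 0; i < n; ++i) { act.push_back(i); acty[i] = y[i]; }
    }
    std::vector<double> d(na);
    for (int q = 0; q < nq; ++q) {
      for (int i = 0; i < na; ++i)
        d[i] = sqdist_cols(query, q, train, act[i], cols);
      P(b, q) = knn_prob_weighted(d, acty, weighted ? actw.data() : NULL, k,
                                  idx);
    }
  }
  return P;
}

// Out-of-bag accuracy of every member of a subset-kNN ensemble: member b
// predicts only its own OOB rows (1-based indices in oob[b]) from its
// in-bag rows restricted to its feature subset, and is scored by the
// fraction of thresholded predictions that match the labels. Members with
// no OOB rows score NA (the caller decides their fate).
// [[Rcpp::export]]
NumericVector cpp_oob_accuracy(NumericMatrix train, IntegerVector y,
                               List subsets, IntegerMatrix W, int k,
                               List oob, double threshold) {
  int n = train.nrow(), B = subsets.size();
  if (W.nrow() != B || W.ncol() != n) stop("weight matrix must be B x n");
  NumericVector acc(B);
  std::vector<int> idx;
  for (int b = 0; b < B; ++b) {
    IntegerVector ob = oob[b];
    if (ob.size() == 0) { acc[b] = NA_REAL; continue; }
    IntegerVector sub = subsets[b];
    std::vector<int> cols(sub.size());
    for (int f = 0; f < (int)cols.size(); ++f) cols[f] = sub[f] - 1;
    std::vector<int> act, actw;
    IntegerVector acty(n);
    int na = 0;
    for (int i = 0; i < n; ++i)
      if (W(b, i) > 0) {
        act.push_back(i);
        actw.push_back(W(b, i));
        acty[na++] = y[i];
      }
    std::vector<double> d(na);
    int correct = 0;
    for (int j = 0; j < ob.size(); ++j) {
      int q = ob[j] - 1;
      for (int i = 0; i < na; ++i)
        d[i] = sqdist_cols(train, q, train, act[i], cols);
      double p = knn_prob_weighted(d, acty, actw.data(), k, idx);
      int pred = p > threshold ? 1 : 0;
      if (pred == y[q]) ++correct;
    }
    acc[b] = (double)correct / (double)ob.size();
  }
  return acc;
}

// Bagged-kNN member probabilities: all members share the full feature set,
// so the neighbour order of every query is computed once and reused; each
// member only filters it through its own bootstrap counts.
// [[Rcpp::export]]
NumericMatrix cpp_members_bagged(NumericMatrix train, IntegerVector y,
                                 NumericMatrix query, IntegerMatrix W,
                                 int k) {
  int n = train.nrow(), nq = query.nrow(), B = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be B x n");
  std::vector<int> cols(train.ncol());
  for (int f = 0; f < (int)cols.size(); ++f) cols[f] = f;
  std::vector<std::vector<int> > orders(nq);
  std::vector<double> d(n);
  for (int q = 0; q < nq; ++q) {
    for (int i = 0; i < n; ++i) d[i] = sqdist_cols(query, q, train, i, cols);
    stable_order(d, orders[q]);
  }
  NumericMatrix P(B, nq);
  std::vector<int> wrow(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) wrow[i] = W(b, i);
    for (int q = 0; q < nq; ++q)
      P(b, q) = prob_from_order(orders[q], n, y, wrow.data(), k, NULL);
  }
  return P;
}
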