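#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Nearest-neighbour ordering used throughout: squared Euclidean distance,
// then training track id, then training row index. Distances accumulate
// coordinate-wise in index order so that results are bit-identical to a
// plain R sum((a - b)^2) oracle.

struct Item {
  double d;
  int trk;
  int idx; // 0-based train row
};

static inline bool item_less(const Item& a, const Item& b) {
  if (a.d != b.d) return a.d < b.d;
  if (a.trk != b.trk) return a.trk < b.trk;
  return a.idx < b.idx;
}

// Fill buf[i] = squared distance from query q to train point i. Train is
// stored one contiguous array per dimension so the loop vectorizes.
static void fill_dist(const std::vector<const double*>& dim, int n, int d,
                      const double* q, double* buf) {
  const double* t0 = dim[0];
  const double q0 = q[0];
  for (int i = 0; i < n; ++i) {
    double f = t0[i] - q0;
    buf[i] = f * f;
  }
  for (int j = 1; j < d; ++j) {
    const double* tj = dim[j];
    const double qj = q[j];
    for (int i = 0; i < n; ++i) {
      double f = tj[i] - qj;
      buf[i] += f * f;
    }
  }
}

// Keep the k best items in an ascending insertion buffer.
static inline void insert_item(std::vector<Item>& best, int k, const Item& it) {
  if ((int)best.size() < k) {
    size_t pos = best.size();
    best.push_back(it);
    while (pos > 0 && item_less(best[pos], best[pos - 1])) {
      std::swap(best[pos], best[pos - 1]);
      --pos;
    }
  } else if (item_less(it, best.back())) {
    size_t pos = k - 1;
    best.back() = it;
    while (pos > 0 && item_less(best[pos], best[pos - 1])) {
      std::swap(best[pos], best[pos - 1]);
      --pos;
    }
  }
}

// Select the k best (distance, track, index) items from the distance buffer.
static void select_k(const double* buf, const int* trk, int n, int k,
                     std::vector<Item>& best) {
  best.clear();
  int warm = k < n ? k : n;
  for (int i = 0; i < warm; ++i) insert_item(best, k, Item{ buf[i], trk[i], i });
  double worst = best.back().d;
  for (int i = warm; i < n; ++i) {
    if (buf[i] > worst) continue; // fast path: most candidates rejected here
    insert_item(best, k, Item{ buf[i], trk[i], i });
    worst = best.back().d;
  }
}

struct KnnContext {
  int n, d;
  std::vector<double> store;          // d contiguous arrays of length n
  std::vector<const double*> dim;
  std::vector<double> buf;
  const int* trk;

  KnnContext(const NumericMatrix& train, const IntegerVector& track)
    : n(train.nrow()), d(train.ncol()), store((size_t)n * d), dim(d),
      buf(n), trk(&track[0]) {
    for (int j = 0; j < d; ++j) {
      double* col = &store[(size_t)j * n];
      for (int i = 0; i < n; ++i) col[i] = train(i, j);
      dim[j] = col;
    }
  }

  void query(const double* q, int k, std::vector<Item>& best) {
    fill_dist(dim, n, d, q, buf.data());
    select_k(buf.data(), trk, n, k, best);
  }
};

static std::vector<double> pack_query(const NumericMatrix& m) {
  int n = m.nrow(), d = m.ncol();
  std::vector<double> out((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      out[(size_t)i * d + j] = m(i, j);
  return out;
}

static void check_args(const NumericMatrix& train, const IntegerVector& track,
                       const NumericMatrix& query, int k) {
  if (query.ncol() != train.ncol()) stop("feature dimension mismatch");
  if (k < 1 || k > train.nrow()) stop("k must be in [1, number of training slices]");
  if (track.size() != train.nrow()) stop("track id per training slice required");
}

// [[Rcpp::export]]
List knn_neighbors_cpp(NumericMatrix train, IntegerVector track,
                       NumericMatrix query, int k) {
  check_args(train, track, query, k);
  int m = query.nrow(), d = train.ncol();
  KnnContext ctx(train, track);
  std::vector<double> qu = pack_query(query);
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<Item> best;
  best.reserve(k + 1);
  for (int qi = 0; qi < m; ++qi) {
    ctx.query(&qu[(size_t)qi * d], k, best);
    for (int j = 0; j < k; ++j) {
      idx(qi, j) = best[j].idx + 1;
      dist(qi, j) = std::sqrt(best[j].d > 0 ? best[j].d : 0.0);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Majority label among the k nearest; label-count ties resolved toward the
// label with the smaller mean neighbour distance, then the smaller label.
// [[Rcpp::export]]
IntegerVector knn_predict_cpp(NumericMatrix train, IntegerVector track,
                              IntegerVector labels, NumericMatrix query, int k) {
  check_args(train, track, query, k);
  if (labels.size() != train.nrow()) stop("one label per training slice required");
  int m = query.nrow(), d = train.ncol();
  KnnContext ctx(train, track);
  std::vector<double> qu = pack_query(query);
  IntegerVector pred(m);
  std::vector<Item> best;
  best.reserve(k + 1);
  std::vector<int> lab, cnt;
  std::vector<double> dsum;
  for (int qi = 0; qi < m; ++qi) {
    ctx.query(&qu[(size_t)qi * d], k, best);
    lab.clear(); cnt.clear(); dsum.clear();
    for (int j = 0; j < k; ++j) {
      int L = labels[best[j].idx];
      double dd = std::sqrt(best[j].d > 0 ? best[j].d : 0.0);
      size_t u = 0;
      for (; u < lab.size(); ++u) if (lab[u] == L) break;
      if (u == lab.size()) { lab.push_back(L); cnt.push_back(0); dsum.push_back(0.0); }
      cnt[u] += 1;
      dsum[u] += dd;
    }
    size_t win = 0;
    for (size_t u = 1; u < lab.size(); ++u) {
      if (cnt[u] > cnt[win]) { win = u; continue; }
      if (cnt[u] == cnt[win]) {
        double mu = dsum[u] / cnt[u], mw = dsum[win] / cnt[win];
        if (mu < mw || (mu == mw && lab[u] < lab[win])) win = u;
      }
    }
    pred[qi] = lab[win];
  }
  return pred;
}
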