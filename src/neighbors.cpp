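// Exact fixed-radius neighbor machinery for the model-free resampling
// estimator.  A k-d tree over z-scored inertial coordinates supports, per
// query sample: the set of reference samples within distance d, minus those
// inside a temporal exclusion window, and the mean instantaneous firing rate
// of those neighbors taken at a set of lag offsets (in samples).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct KDTree {
  const double *pts; // column-major n x k
  int n, k;
  std::vector<int> idx;     // point order
  std::vector<int> splitdim;
  std::vector<double> splitval;
  std::vector<int> left, right, start, end; // node ranges into idx
  int leaf_size = 16;

  double coord(int i, int d) const { return pts[(size_t)d * n + i]; }

  int build(int s, int e) {
    int node = (int)splitdim.size();
    splitdim.push_back(-1); splitval.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    start.push_back(s); end.push_back(e);
    if (e - s <= leaf_size) return node;
    // split on dimension of max spread
    int bd = 0; double bs = -1.0;
    for (int d = 0; d < k; ++d) {
      double lo = coord(idx[s], d), hi = lo;
      for (int i = s + 1; i < e; ++i) {
        double v = coord(idx[i], d);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi - lo > bs) { bs = hi - lo; bd = d; }
    }
    if (bs <= 0.0) return node; // all identical -> leaf
    int m = (s + e) / 2;
    std::nth_element(idx.begin() + s, idx.begin() + m, idx.begin() + e,
                     [&](int a, int b) { return coord(a, bd) < coord(b, bd); });
    splitdim[node] = bd;
    splitval[node] = coord(idx[m], bd);
    int l = build(s, m);
    left[node] = l;
    int r = build(m, e);
    right[node] = r;
    return node;
  }

  void init(const double *p, int n_, int k_) {
    pts = p; n = n_; k = k_;
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n);
  }

  void radius_search(const double *qpt, double r2, std::vector<int> &out,
                     int node = 0) const {
    if (splitdim[node] < 0) {
      for (int i = start[node]; i < end[node]; ++i) {
        int p = idx[i];
        double s = 0.0;
        for (int d = 0; d < k; ++d) {
          double diff = coord(p, d) - qpt[d];
          s += diff * diff;
          if (s > r2) break;
        }
        if (s <= r2) out.push_back(p);
      }
      return;
    }
    double diff = qpt[splitdim[node]] - splitval[node];
    if (diff <= 0.0) {
      radius_search(qpt, r2, out, left[node]);
      if (diff * diff <= r2) radius_search(qpt, r2, out, right[node]);
    } else {
      radius_search(qpt, r2, out, right[node]);
      if (diff * diff <= r2) radius_search(qpt, r2, out, left[node]);
    }
  }
};

} // namespace

// Scan over lag offsets.  ref/query: n x k and m x k z-scored coordinate
// matrices.  fr: full-recording instantaneous firing rate on the uniform
// grid; ref_idx/query_idx: 1-based indices of the rows into that grid so the
// rate of a neighbor at lag `off` samples is fr[ref_idx[j] + off].
// exclude_window > 0 applies |t_ref - t_query| <= w exclusion (same
// recording).  Returns, per lag: Pearson r between the estimate and
// fr[query_idx + off], the estimate itself (if return_rho), per-query
// neighbor count and coverage.
// [[Rcpp::export]]
List cpp_neighbor_scan(NumericMatrix ref, NumericVector ref_t,
                       IntegerVector ref_idx, NumericVector fr_ref,
                       NumericMatrix query, NumericVector query_t,
                       IntegerVector query_idx, NumericVector fr_query,
                       IntegerVector offsets,
                       double d, double w, bool exclude_window,
                       int min_neighbors, bool return_rho) {
  int n = ref.nrow(), m = query.nrow(), k = ref.ncol(), L = offsets.size();
  int nfr = fr_ref.size(), nfq = fr_query.size();
  KDTree tree;
  tree.init(REAL(ref), n, k);
  double r2 = d * d;

  NumericMatrix rho;
  if (return_rho) rho = NumericMatrix(m, L);
  IntegerVector count(m);
  // accumulators for Pearson r per lag
  std::vector<double> sx(L, 0), sy(L, 0), sxx(L, 0), syy(L, 0), sxy(L, 0);
  std::vector<int> npair(L, 0), ncov(L, 0);

  std::vector<int> nb;
  std::vector<double> qpt(k);
  for (int i = 0; i < m; ++i) {
    for (int d2 = 0; d2 < k; ++d2) qpt[d2] = query(i, d2);
    nb.clear();
    tree.radius_search(qpt.data(), r2, nb);
    double ti = query_t[i];
    int nkept = 0;
    // temporal exclusion
    if (exclude_window) {
      for (size_t jj = 0; jj < nb.size(); ++jj) {
        if (std::fabs(ref_t[nb[jj]] - ti) > w) nb[nkept++] = nb[jj];
      }
    } else {
      nkept = (int)nb.size();
    }
    count[i] = nkept;
    for (int l = 0; l < L; ++l) {
      int off = offsets[l];
      double s = 0.0;
      int c = 0;
      for (int jj = 0; jj < nkept; ++jj) {
        int fj = ref_idx[nb[jj]] - 1 + off;
        if (fj >= 0 && fj < nfr) {
          double v = fr_ref[fj];
          if (R_finite(v)) { s += v; ++c; }
        }
      }
      double est = (c >= min_neighbors && c > 0) ? s / c : NA_REAL;
      if (return_rho) rho(i, l) = est;
      if (R_finite(est)) {
        ++ncov[l];
        int fi = query_idx[i] - 1 + off;
        if (fi >= 0 && fi < nfq && R_finite(fr_query[fi])) {
          double y = fr_query[fi];
          sx[l] += est; sy[l] += y; sxx[l] += est * est; syy[l] += y * y;
          sxy[l] += est * y; ++npair[l];
        }
      }
    }
  }

  NumericVector r(L), coverage(L);
  for (int l = 0; l < L; ++l) {
    coverage[l] = m > 0 ? (double)ncov[l] / m : NA_REAL;
    if (npair[l] >= 3) {
      double nn = npair[l];
      double cov = sxy[l] - sx[l] * sy[l] / nn;
      double vx = sxx[l] - sx[l] * sx[l] / nn;
      double vy = syy[l] - sy[l] * sy[l] / nn;
      r[l] = (vx > 0 && vy > 0) ? cov / std::sqrt(vx * vy) : NA_REAL;
    } else {
      r[l] = NA_REAL;
    }
  }
  List out = List::create(_["r"] = r, _["coverage"] = coverage,
                          _["count"] = count, _["n_pairs"] = npair);
  if (return_rho) out["rho"] = rho;
  return out;
}

// Distance to the kth nearest neighbor (brute force) for a subsample of
// queries; used to tune the neighbor radius d.
// [[Rcpp::export]]
NumericVector cpp_kth_distance(NumericMatrix ref, NumericMatrix query,
                               int kth) {
  int n = ref.nrow(), m = query.nrow(), k = ref.ncol();
  NumericVector out(m);
  std::vector<double> d2(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int d = 0; d < k; ++d) {
        double diff = ref(j, d) - query(i, d);
        s += diff * diff;
      }
      d2[j] = s;
    }
    int kk = std::min(kth, n) - 1;
    std::nth_element(d2.begin(), d2.begin() + kk, d2.end());
    out[i] = std::sqrt(d2[kk]);
  }
  return out;
}
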