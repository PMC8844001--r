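#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Cityblock (L1) distances between each row of x and each row of centroids.
// [[Rcpp::export(name = ".l1_dist_cpp")]]
NumericMatrix l1_dist_cpp(const NumericMatrix& x, const NumericMatrix& centroids) {
  const int w = x.nrow(), p = x.ncol(), k = centroids.nrow();
  if (centroids.ncol() != p) stop("dimension mismatch");
  NumericMatrix d(w, k);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < p; ++c) {
      const double cc = centroids(j, c);
      const double* xc = &x(0, c);
      double* dj = &d(0, j);
      for (int i = 0; i < w; ++i) dj[i] += std::fabs(xc[i] - cc);
    }
  }
  return d;
}

// Component-wise median of the rows selected by 1-based indices idx.
// [[Rcpp::export(name = ".col_medians_cpp")]]
NumericVector col_medians_cpp(const NumericMatrix& x, const IntegerVector& idx) {
  const int n = idx.size(), p = x.ncol();
  if (n == 0) stop("empty cluster");
  NumericVector out(p);
  std::vector<double> buf(n);
  for (int c = 0; c < p; ++c) {
    for (int i = 0; i < n; ++i) buf[i] = x(idx[i] - 1, c);
    const int mid = n / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      m = (m + lo) / 2.0;
    }
    out[c] = m;
  }
  return out;
}

static double col_median_subset(const NumericMatrix& x,
                                const std::vector<int>& rows, int c,
                                std::vector<double>& buf) {
  const int n = (int)rows.size();
  buf.resize(n);
  for (int i = 0; i < n; ++i) buf[i] = x(rows[i], c);
  const int mid = n / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
  double m = buf[mid];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + mid);
    m = (m + lo) / 2.0;
  }
  return m;
}

// One full Lloyd run of cityblock k-means with component-wise median
// updates. init is a vector of k 1-based row indices for the initial
// centroids (chosen in R so determinism follows R's RNG). Empty clusters
// are re-seeded from the point farthest from its assigned centroid.
// Returns labels (1-based), centroids, inertia and the iteration count.
// [[Rcpp::export(name = ".kmedians_fit_cpp")]]
List kmedians_fit_cpp(const NumericMatrix& x, const IntegerVector& init,
                      const int max_iter) {
  const int w = x.nrow(), p = x.ncol(), k = init.size();
  NumericMatrix centroids(k, p);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < p; ++c) centroids(j, c) = x(init[j] - 1, c);

  IntegerVector labels(w, 0);
  std::vector<double> mind(w);
  double inertia = R_PosInf;
  int iter = 0;
  std::vector<double> buf;
  std::vector<std::vector<int>> members(k);

  NumericMatrix d(w, k);
  while (iter < max_iter) {
    ++iter;
    // assignment (column-outer accumulation for cache locality)
    bool changed = false;
    for (int j = 0; j < k; ++j) members[j].clear();
    std::fill(d.begin(), d.end(), 0.0);
    for (int j = 0; j < k; ++j) {
      double* dj = &d(0, j);
      for (int c = 0; c < p; ++c) {
        const double cc = centroids(j, c);
        const double* xc = &x(0, c);
        for (int i = 0; i < w; ++i) dj[i] += std::fabs(xc[i] - cc);
      }
    }
    for (int i = 0; i < w; ++i) {
      double best = R_PosInf;
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        if (d(i, j) < best) { best = d(i, j); bj = j + 1; }
      }
      if (labels[i] != bj) { labels[i] = bj; changed = true; }
      mind[i] = best;
    }
    for (int i = 0; i < w; ++i) members[labels[i] - 1].push_back(i);
    // re-seed empty clusters from the farthest point
    for (int j = 0; j < k; ++j) {
      if (members[j].empty()) {
        int far = (int)(std::max_element(mind.begin(), mind.end()) - mind.begin());
        int old = labels[far] - 1;
        members[old].erase(std::find(members[old].begin(), members[old].end(), far));
        for (int c = 0; c < p; ++c) centroids(j, c) = x(far, c);
        labels[far] = j + 1;
        members[j].push_back(far);
        mind[far] = 0.0;
        changed = true;
      }
    }
    double new_inertia = 0.0;
    for (int i = 0; i < w; ++i) new_inertia += mind[i];
    if (new_inertia > inertia + 1e-8 * std::max(1.0, std::fabs(inertia)))
      stop("internal error: inertia increased during Lloyd iteration");
    inertia = new_inertia;
    if (!changed) break;
    // median update
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < p; ++c)
        centroids(j, c) = col_median_subset(x, members[j], c, buf);
  }
  return List::create(_["labels"] = labels, _["centroids"] = centroids,
                      _["inertia"] = inertia, _["iterations"] = iter);
}
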