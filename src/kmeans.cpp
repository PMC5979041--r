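#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sqdist(const NumericMatrix &X, int i,
                            const std::vector<double> &c, int dim) {
  double s = 0.0;
  for (int d = 0; d < dim; ++d) {
    double dx = X(i, d) - c[d];
    s += dx * dx;
  }
  return s;
}

// Lloyd k-means with k-means++ seeding.  Determinism contract: R RNG drives
// the initialization (set.seed upstream), nearest-center ties break to the
// lowest center index (strict < comparison), empty clusters are re-seeded
// from the point farthest from its current center.
// [[Rcpp::export]]
List cpp_kmeans(NumericMatrix X, int k, int max_iter, double tol) {
  int n = X.nrow(), dim = X.ncol();
  if (n < k) stop("fewer frames than clusters");
  std::vector<std::vector<double>> centers(k, std::vector<double>(dim));
  // k-means++ init
  {
    int first = (int)std::floor(unif_rand() * n);
    if (first >= n) first = n - 1;
    for (int d = 0; d < dim; ++d) centers[0][d] = X(first, d);
    std::vector<double> d2(n);
    for (int c = 1; c < k; ++c) {
      double tot = 0.0;
      for (int i = 0; i < n; ++i) {
        double best = R_PosInf;
        for (int cc = 0; cc < c; ++cc) {
          double s = sqdist(X, i, centers[cc], dim);
          if (s < best) best = s;
        }
        d2[i] = best;
        tot += best;
      }
      int pick = 0;
      if (tot > 0) {
        double u = unif_rand() * tot, acc = 0.0;
        for (int i = 0; i < n; ++i) {
          acc += d2[i];
          if (acc >= u) { pick = i; break; }
        }
      } else {
        pick = (int)std::floor(unif_rand() * n);
        if (pick >= n) pick = n - 1;
      }
      for (int d = 0; d < dim; ++d) centers[c][d] = X(pick, d);
    }
  }
  IntegerVector assign(n);
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bc = 0;
      for (int c = 0; c < k; ++c) {
        double s = sqdist(X, i, centers[c], dim);
        if (s < best) { best = s; bc = c; }
      }
      if (assign[i] != bc + 1) { changed = true; assign[i] = bc + 1; }
    }
    std::vector<std::vector<double>> nc(k, std::vector<double>(dim, 0.0));
    std::vector<int> cnt(k, 0);
    for (int i = 0; i < n; ++i) {
      int c = assign[i] - 1;
      ++cnt[c];
      for (int d = 0; d < dim; ++d) nc[c][d] += X(i, d);
    }
    for (int c = 0; c < k; ++c) {
      if (cnt[c] == 0) {
        // re-seed from the globally farthest point
        double best = -1.0;
        int bi = 0;
        for (int i = 0; i < n; ++i) {
          double s = sqdist(X, i, centers[assign[i] - 1], dim);
          if (s > best) { best = s; bi = i; }
        }
        for (int d = 0; d < dim; ++d) nc[c][d] = X(bi, d);
        cnt[c] = 1;
        changed = true;
      }
    }
    double move = 0.0;
    for (int c = 0; c < k; ++c)
      for (int d = 0; d < dim; ++d) {
        double v = nc[c][d] / cnt[c];
        move = std::max(move, std::fabs(v - centers[c][d]));
        centers[c][d] = v;
      }
    if (!changed || move < tol) { ++iter; break; }
  }
  // final assignment against converged centers
  double wss = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bc = 0;
    for (int c = 0; c < k; ++c) {
      double s = sqdist(X, i, centers[c], dim);
      if (s < best) { best = s; bc = c; }
    }
    assign[i] = bc + 1;
    wss += best;
  }
  NumericMatrix C(k, dim);
  for (int c = 0; c < k; ++c)
    for (int d = 0; d < dim; ++d) C(c, d) = centers[c][d];
  return List::create(_["assignments"] = assign, _["centers"] = C,
                      _["iterations"] = iter, _["tot_withinss"] = wss);
}

// [[Rcpp::export]]
IntegerVector cpp_assign_clusters(NumericMatrix X, NumericMatrix centers) {
  int n = X.nrow(), dim = X.ncol(), k = centers.nrow();
  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bc = 0;
    for (int c = 0; c < k; ++c) {
      double s = 0.0;
      for (int d = 0; d < dim; ++d) {
        double dx = X(i, d) - centers(c, d);
        s += dx * dx;
      }
      if (s < best) { best = s; bc = c; }
    }
    assign[i] = bc + 1;
  }
  return assign;
}
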