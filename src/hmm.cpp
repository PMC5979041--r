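#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Baum-Welch for a discrete-emission HMM over multiple observation sequences
// (scaled forward-backward).  obs holds 1-based symbol indices, concatenated;
// seq_len gives the length of each sequence.  A0 (n x n), B0 (n x m), pi0 (n)
// are the initial estimates.  Returns updated parameters and the per-iteration
// log-likelihood trace; the caller enforces the EM monotonicity guard.
// [[Rcpp::export]]
List cpp_hmm_em(IntegerVector obs, IntegerVector seq_len, NumericMatrix A0,
                NumericMatrix B0, NumericVector pi0, int max_iter,
                double tol) {
  int n = A0.nrow(), m = B0.ncol(), nseq = seq_len.size();
  long total = obs.size();
  std::vector<double> A(A0.begin(), A0.end());   // column-major n x n
  std::vector<double> B(B0.begin(), B0.end());   // column-major n x m
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> alpha(total * n), beta(total * n), scale(total);
  std::vector<double> logliks;
  double prev_ll = R_NegInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    std::vector<double> Anum(n * n, 0.0), Bnum(n * m, 0.0), piacc(n, 0.0),
        Aden(n, 0.0);
    double ll = 0.0;
    long off = 0;
    for (int q = 0; q < nseq; ++q) {
      long Tq = seq_len[q];
      // forward
      for (long t = 0; t < Tq; ++t) {
        int o = obs[off + t] - 1;
        double s = 0.0;
        if (t == 0) {
          for (int i = 0; i < n; ++i) {
            double v = pi[i] * B[i + (long)o * n];
            alpha[(off + t) * n + i] = v;
            s += v;
          }
        } else {
          for (int j = 0; j < n; ++j) {
            double v = 0.0;
            for (int i = 0; i < n; ++i)
              v += alpha[(off + t - 1) * n + i] * A[i + (long)j * n];
            v *= B[j + (long)o * n];
            alpha[(off + t) * n + j] = v;
            s += v;
          }
        }
        if (s <= 0) stop("zero forward probability (symbol unreachable)");
        scale[off + t] = s;
        ll += std::log(s);
        for (int i = 0; i < n; ++i) alpha[(off + t) * n + i] /= s;
      }
      // backward
      for (int i = 0; i < n; ++i) beta[(off + Tq - 1) * n + i] = 1.0;
      for (long t = Tq - 2; t >= 0; --t) {
        int o = obs[off + t + 1] - 1;
        for (int i = 0; i < n; ++i) {
          double v = 0.0;
          for (int j = 0; j < n; ++j)
            v += A[i + (long)j * n] * B[j + (long)o * n] *
                 beta[(off + t + 1) * n + j];
          beta[(off + t) * n + i] = v / scale[off + t + 1];
        }
      }
      // accumulate expected counts
      for (long t = 0; t < Tq; ++t) {
        int o = obs[off + t] - 1;
        double norm = 0.0;
        for (int i = 0; i < n; ++i)
          norm += alpha[(off + t) * n + i] * beta[(off + t) * n + i];
        for (int i = 0; i < n; ++i) {
          double g = alpha[(off + t) * n + i] * beta[(off + t) * n + i] / norm;
          Bnum[i + (long)o * n] += g;
          if (t == 0) piacc[i] += g;
        }
      }
      for (long t = 0; t < Tq - 1; ++t) {
        int o = obs[off + t + 1] - 1;
        for (int i = 0; i < n; ++i) {
          double ai = alpha[(off + t) * n + i];
          for (int j = 0; j < n; ++j) {
            double xi = ai * A[i + (long)j * n] * B[j + (long)o * n] *
                        beta[(off + t + 1) * n + j] / scale[off + t + 1];
            Anum[i + (long)j * n] += xi;
            Aden[i] += xi;
          }
        }
      }
      off += Tq;
    }
    logliks.push_back(ll);
    // M-step
    for (int i = 0; i < n; ++i) {
      if (Aden[i] > 0)
        for (int j = 0; j < n; ++j) A[i + (long)j * n] = Anum[i + (long)j * n] / Aden[i];
      double bs = 0.0;
      for (int o = 0; o < m; ++o) bs += Bnum[i + (long)o * n];
      if (bs > 0)
        for (int o = 0; o < m; ++o) B[i + (long)o * n] = Bnum[i + (long)o * n] / bs;
    }
    double ps = 0.0;
    for (int i = 0; i < n; ++i) ps += piacc[i];
    for (int i = 0; i < n; ++i) pi[i] = piacc[i] / ps;
    if (it > 0 && std::fabs(ll - prev_ll) < tol) { prev_ll = ll; ++it; break; }
    prev_ll = ll;
  }
  NumericMatrix Aout(n, n), Bout(n, m);
  std::copy(A.begin(), A.end(), Aout.begin());
  std::copy(B.begin(), B.end(), Bout.begin());
  return List::create(_["A"] = Aout, _["B"] = Bout, _["pi"] = wrap(pi),
                      _["loglik"] = wrap(logliks), _["iterations"] = it);
}

// Sample a discrete-time Markov chain (1-based states) with R's RNG.
// [[Rcpp::export]]
IntegerVector cpp_markov_sample(NumericMatrix T, int start, double n_steps) {
  int n = T.nrow();
  long ns = (long)n_steps;
  IntegerVector out(ns + 1);
  int s = start;
  out[0] = s;
  for (long t = 0; t < ns; ++t) {
    double u = unif_rand(), acc = 0.0;
    int nx = n;
    for (int j = 0; j < n; ++j) {
      acc += T(s - 1, j);
      if (u <= acc) { nx = j + 1; break; }
    }
    if (nx > n) nx = n;
    s = nx;
    out[t + 1] = s;
  }
  return out;
}

// First-hit Monte Carlo: from `start`, run until the chain enters set A or
// set B; returns number of B-first hits out of nrep, plus hitting steps.
// [[Rcpp::export]]
List cpp_mc_first_hit(NumericMatrix T, IntegerVector Aset, IntegerVector Bset,
                      int start, int nrep, double max_steps) {
  int n = T.nrow();
  std::vector<int> inA(n + 1, 0), inB(n + 1, 0);
  for (int i = 0; i < Aset.size(); ++i) inA[Aset[i]] = 1;
  for (int i = 0; i < Bset.size(); ++i) inB[Bset[i]] = 1;
  int hitsB = 0, done = 0;
  NumericVector steps(nrep);
  for (int r = 0; r < nrep; ++r) {
    int s = start;
    long t = 0;
    long mx = (long)max_steps;
    while (t < mx) {
      if (inB[s]) { ++hitsB; break; }
      if (inA[s]) break;
      double u = unif_rand(), acc = 0.0;
      int nx = n;
      for (int j = 0; j < n; ++j) {
        acc += T(s - 1, j);
        if (u <= acc) { nx = j + 1; break; }
      }
      s = nx > n ? n : nx;
      ++t;
    }
    steps[r] = (double)t;
    if (t < mx) ++done;
  }
  return List::create(_["hitsB"] = hitsB, _["completed"] = done,
                      _["steps"] = steps);
}

// Mean-first-passage Monte Carlo for a discrete chain: steps to first enter
// target set, nrep independent replicates from `start`.
// [[Rcpp::export]]
NumericVector cpp_mc_first_passage(NumericMatrix T, IntegerVector target,
                                   int start, int nrep, double max_steps) {
  int n = T.nrow();
  std::vector<int> inB(n + 1, 0);
  for (int i = 0; i < target.size(); ++i) inB[target[i]] = 1;
  NumericVector steps(nrep);
  for (int r = 0; r < nrep; ++r) {
    int s = start;
    long t = 0;
    long mx = (long)max_steps;
    while (!inB[s] && t < mx) {
      double u = unif_rand(), acc = 0.0;
      int nx = n;
      for (int j = 0; j < n; ++j) {
        acc += T(s - 1, j);
        if (u <= acc) { nx = j + 1; break; }
      }
      s = nx > n ? n : nx;
      ++t;
    }
    steps[r] = (double)t;
  }
  return steps;
}
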