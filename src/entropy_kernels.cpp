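#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// O(N^2) kernels for the template-matching entropies. Distances are
// Chebyshev (max-norm) throughout.

static double apen_phi(const NumericVector& x, int m, double r) {
  int N = x.size();
  int M = N - m + 1;
  double s = 0.0;
  for (int i = 0; i < M; ++i) {
    int cnt = 0;
    for (int j = 0; j < M; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) ++cnt; // self-match included
    }
    s += std::log((double)cnt / M);
  }
  return s / M;
}

// [[Rcpp::export]]
double cpp_apen(NumericVector x, int m, double r) {
  return apen_phi(x, m, r) - apen_phi(x, m + 1, r);
}

// Sample entropy match counts: B = template pairs (i < j) within r at
// length m, A = within r at length m + 1; both over the N - m templates
// whose (m+1)-extension exists.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int N = x.size();
  int M = N - m; // templates with an (m+1)-th sample available
  double A = 0.0, B = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        double a = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, a) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

static double fuzzy_phi(const NumericVector& x, int m, double r, double nexp) {
  int N = x.size();
  int M = N - m; // same template count at both lengths
  std::vector<double> mean(M);
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    mean[i] = s / m;
  }
  double tot = 0.0;
  long cnt = 0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs((x[i + k] - mean[i]) - (x[j + k] - mean[j]));
        if (a > d) d = a;
      }
      tot += std::exp(-std::pow(d / r, nexp));
      ++cnt;
    }
  }
  return tot / cnt;
}

// [[Rcpp::export]]
double cpp_fuzzyen(NumericVector x, int m, double r, double nexp) {
  double pm = fuzzy_phi(x, m, r, nexp);
  double pm1 = fuzzy_phi(x, m + 1, r, nexp);
  return -std::log(pm1 / pm);
}

// Escape-time statistics for the maximum-likelihood second-order
// Kolmogorov entropy: for every ordered pair of embedded points initially
// within r0 (Chebyshev, embedding dimension m, delay 1), b = number of
// consecutive time steps (including the first) the pair stays within r0.
// Returns (number of pairs, mean b).
// [[Rcpp::export]]
NumericVector cpp_k2_escape(NumericVector x, int m, double r0) {
  int N = x.size();
  int Nv = N - m + 1; // embedded vectors
  if (Nv < 2) return NumericVector::create(0.0, NA_REAL);
  double total_b = 0.0;
  double npairs = 0.0;
  std::vector<int> within(Nv);
  for (int off = 1; off < Nv; ++off) {
    int L = Nv - off; // pairs (i, i + off), i = 0..L-1
    for (int i = 0; i < L; ++i) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[i + off + k]);
        if (a > d) d = a;
        if (d > r0) break;
      }
      within[i] = (d <= r0) ? 1 : 0;
    }
    // run length of consecutive 'within' starting at each i, by reverse scan
    int run = 0;
    std::vector<int> blen(L);
    for (int i = L - 1; i >= 0; --i) {
      run = within[i] ? run + 1 : 0;
      blen[i] = run;
    }
    for (int i = 0; i < L; ++i) {
      if (within[i]) {
        total_b += blen[i];
        npairs += 1.0;
      }
    }
  }
  double bbar = npairs > 0 ? total_b / npairs : NA_REAL;
  return NumericVector::create(npairs, bbar);
}
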