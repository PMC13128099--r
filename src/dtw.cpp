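// Dynamic time warping between multivariate sequences (rows = time points),
// with Euclidean pointwise distance. Classic O(N*M) dynamic program over
// monotone warping paths with steps (1,0), (0,1), (1,1); no band constraint.
#include <Rcpp.h>
using namespace Rcpp;

static inline double rowdist(const NumericMatrix& a, int i,
                             const NumericMatrix& b, int j) {
  double s = 0.0;
  const int d = a.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = a(i, k) - b(j, k);
    s += diff * diff;
  }
  return std::sqrt(s);
}

static double dtw_core(const NumericMatrix& a, const NumericMatrix& b) {
  const int n = a.nrow(), m = b.nrow();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      const double c = rowdist(a, i - 1, b, j - 1);
      cur[j] = c + std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double cpp_dtw(NumericMatrix a, NumericMatrix b) {
  return dtw_core(a, b);
}

// DTW with backtracked optimal path. Ties resolved deterministically:
// diagonal preferred, then the shorter-i predecessor, then shorter-j.
// [[Rcpp::export]]
List cpp_dtw_path(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericMatrix D(n + 1, m + 1);
  std::fill(D.begin(), D.end(), R_PosInf);
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double c = rowdist(a, i - 1, b, j - 1);
      D(i, j) = c + std::min(D(i - 1, j - 1),
                             std::min(D(i - 1, j), D(i, j - 1)));
    }
  }
  std::vector<int> pi, pj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    pi.push_back(i);
    pj.push_back(j);
    if (i == 1 && j == 1) break;
    const double c = D(i, j) - rowdist(a, i - 1, b, j - 1);
    if (i > 1 && j > 1 && std::abs(D(i - 1, j - 1) - c) <= 1e-12) {
      --i; --j;
    } else if (i > 1 && std::abs(D(i - 1, j) - c) <= 1e-12) {
      --i;
    } else {
      --j;
    }
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int l = 0; l < L; ++l) {
    path(l, 0) = pi[L - 1 - l];
    path(l, 1) = pj[L - 1 - l];
  }
  return List::create(_["distance"] = D(n, m), _["path"] = path);
}

// [[Rcpp::export]]
NumericMatrix cpp_dtw_pairwise(List seqs) {
  const int n = seqs.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix a = seqs[i];
    for (int j = i + 1; j < n; ++j) {
      NumericMatrix b = seqs[j];
      const double d = dtw_core(a, b);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// [[Rcpp::export]]
NumericMatrix cpp_dtw_cross(List seqs, List centroids) {
  const int n = seqs.size(), k = centroids.size();
  NumericMatrix D(n, k);
  for (int i = 0; i < n; ++i) {
    NumericMatrix a = seqs[i];
    for (int j = 0; j < k; ++j) {
      NumericMatrix b = centroids[j];
      D(i, j) = dtw_core(a, b);
    }
  }
  return D;
}
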