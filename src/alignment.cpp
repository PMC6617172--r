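#include <Rcpp.h>
using namespace Rcpp;

// Local-alignment score matrix H for two integer-encoded sequences.
// sim is the residue-similarity matrix (values in (0,1]); d the linear gap
// penalty. Row 0 / column 0 stay zero and every entry is clamped at zero.
static inline double cell_max(double diag, double up, double left) {
  double m = diag;
  if (up > m) m = up;
  if (left > m) m = left;
  return m > 0.0 ? m : 0.0;
}

// [[Rcpp::export]]
NumericMatrix align_matrix_cpp(IntegerVector a, IntegerVector b,
                               NumericMatrix sim, double d) {
  int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) {
    int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      int bj = b[j - 1] - 1;
      H(i, j) = cell_max(H(i - 1, j - 1) + sim(ai, bj),
                         H(i - 1, j) - d,
                         H(i, j - 1) - d);
    }
  }
  return H;
}

// [[Rcpp::export]]
double align_max_cpp(IntegerVector a, IntegerVector b,
                     NumericMatrix sim, double d) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    int ai = a[i - 1] - 1;
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      int bj = b[j - 1] - 1;
      double h = cell_max(prev[j - 1] + sim(ai, bj),
                          prev[j] - d,
                          cur[j - 1] - d);
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(prev, cur);
  }
  return best;
}

// All pairwise maxH scores for a list of integer-encoded sequences
// (diagonal = sequence length, the self-alignment score).
// [[Rcpp::export]]
NumericMatrix maxh_matrix_cpp(List seqs, NumericMatrix sim, double d) {
  int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    out(i, i) = (double)sv[i].size();
    for (int j = i + 1; j < n; ++j) {
      double mh = align_max_cpp(sv[i], sv[j], sim, d);
      out(i, j) = mh;
      out(j, i) = mh;
    }
  }
  return out;
}

// Cross maxH scores between two lists of integer-encoded sequences.
// [[Rcpp::export]]
NumericMatrix maxh_cross_cpp(List seqs1, List seqs2,
                             NumericMatrix sim, double d) {
  int n1 = seqs1.size(), n2 = seqs2.size();
  NumericMatrix out(n1, n2);
  for (int i = 0; i < n1; ++i) {
    IntegerVector a = as<IntegerVector>(seqs1[i]);
    for (int j = 0; j < n2; ++j)
      out(i, j) = align_max_cpp(a, as<IntegerVector>(seqs2[j]), sim, d);
  }
  return out;
}
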