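#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch style edit-distance DP used by optimal matching:
// D[i][j] = min(D[i-1][j-1] + sub(s1_i, s2_j),
//               D[i-1][j]   + indel,
//               D[i][j-1]   + indel),
// with D[i][0] = i * indel, D[0][j] = j * indel.
static double om_pair(const int* s1, int n1, const int* s2, int n2,
                      const NumericMatrix& sub, double indel,
                      std::vector<double>& prev, std::vector<double>& cur) {
  for (int j = 0; j <= n2; ++j) prev[j] = j * indel;
  for (int i = 1; i <= n1; ++i) {
    cur[0] = i * indel;
    const int a = s1[i - 1];
    for (int j = 1; j <= n2; ++j) {
      double best = prev[j - 1] + sub(a, s2[j - 1]);
      double del = prev[j] + indel;
      if (del < best) best = del;
      double ins = cur[j - 1] + indel;
      if (ins < best) best = ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[n2];
}

// [[Rcpp::export]]
double om_dist_pair_cpp(IntegerVector s1, IntegerVector s2,
                        NumericMatrix sub, double indel) {
  int n1 = s1.size(), n2 = s2.size();
  std::vector<double> prev(n2 + 1), cur(n2 + 1);
  return om_pair(&s1[0], n1, &s2[0], n2, sub, indel, prev, cur);
}

// Full pairwise matrix for equal-length sequences stored as rows of an
// integer matrix (0-based state codes).
// [[Rcpp::export]]
NumericMatrix om_dist_matrix_cpp(IntegerMatrix seqs, NumericMatrix sub,
                                 double indel) {
  int n = seqs.nrow(), L = seqs.ncol();
  NumericMatrix out(n, n);
  std::vector<int> buf(n * L);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j) buf[i * L + j] = seqs(i, j);
  std::vector<double> prev(L + 1), cur(L + 1);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = om_pair(&buf[i * L], L, &buf[j * L], L, sub, indel, prev, cur);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
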