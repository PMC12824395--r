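#include <Rcpp.h>
using namespace Rcpp;

// Optimal-matching edit distance between two integer-coded sequences by
// dynamic programming over substitution (cost matrix) and indel moves.
static double om_pair(const IntegerMatrix& seqs, int a, int b,
                      const NumericMatrix& sub, double indel,
                      std::vector<double>& prev, std::vector<double>& cur) {
  const int L = seqs.ncol();
  for (int j = 0; j <= L; ++j) prev[j] = j * indel;
  for (int i = 1; i <= L; ++i) {
    cur[0] = i * indel;
    const int ai = seqs(a, i - 1) - 1;
    for (int j = 1; j <= L; ++j) {
      const int bj = seqs(b, j - 1) - 1;
      double best = prev[j - 1] + sub(ai, bj);
      double del = prev[j] + indel;
      double ins = cur[j - 1] + indel;
      if (del < best) best = del;
      if (ins < best) best = ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[L];
}

// [[Rcpp::export(name = ".om_dist_matrix")]]
NumericMatrix om_dist_matrix(IntegerMatrix seqs, NumericMatrix sub,
                             double indel) {
  const int n = seqs.nrow();
  const int L = seqs.ncol();
  NumericMatrix out(n, n);
  std::vector<double> prev(L + 1), cur(L + 1);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double d = om_pair(seqs, a, b, sub, indel, prev, cur);
      out(a, b) = d;
      out(b, a) = d;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".om_dist_pair")]]
double om_dist_pair(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double indel) {
  const int La = a.size(), Lb = b.size();
  std::vector<double> prev(Lb + 1), cur(Lb + 1);
  for (int j = 0; j <= Lb; ++j) prev[j] = j * indel;
  for (int i = 1; i <= La; ++i) {
    cur[0] = i * indel;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= Lb; ++j) {
      const int bj = b[j - 1] - 1;
      double best = prev[j - 1] + sub(ai, bj);
      double del = prev[j] + indel;
      double ins = cur[j - 1] + indel;
      if (del < best) best = del;
      if (ins < best) best = ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[Lb];
}
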