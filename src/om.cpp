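#include <Rcpp.h>
using namespace Rcpp;

// Optimal-matching (Levenshtein-type) edit distance between two integer
// state sequences with an arbitrary symmetric substitution-cost matrix and a
// constant insertion/deletion cost. Standard (m+1) x (n+1) dynamic program,
// rolling two rows.
// [[Rcpp::export]]
double om_dist_cpp(IntegerVector s1, IntegerVector s2,
                   NumericMatrix sub, double indel) {
  int m = s1.size(), n = s2.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j * indel;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * indel;
    int a = s1[i - 1] - 1;
    for (int j = 1; j <= n; ++j) {
      int b = s2[j - 1] - 1;
      double d = prev[j - 1] + sub(a, b);        // substitution (0 if equal)
      double del = prev[j] + indel;
      double ins = cur[j - 1] + indel;
      cur[j] = std::min(d, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
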