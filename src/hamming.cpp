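#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance between one encoded k-mer and a block of columns of the
// encoded point matrix. Codes are small integers (acgt -> 1..4, other -> 0);
// code 0 never matches anything, including itself.

// [[Rcpp::export(name = ".hamming_block")]]
IntegerVector hamming_block(const IntegerMatrix& mat, const IntegerVector& idx,
                            const IntegerVector& q) {
  const int k = mat.nrow();
  if (q.size() != k) stop("query length does not match matrix rows");
  const int n = idx.size();
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) {
    const int col = idx[j] - 1;
    if (col < 0 || col >= mat.ncol()) stop("column index out of range");
    int d = 0;
    for (int i = 0; i < k; ++i) {
      const int a = mat(i, col), b = q[i];
      if (a != b || a == 0) ++d;
    }
    out[j] = d;
  }
  return out;
}

// Mismatch count of `read` against every full window of `genome`
// (both encoded). Returns integer vector of length L - k + 1 (or length 0).

// [[Rcpp::export(name = ".sliding_hamming")]]
IntegerVector sliding_hamming(const IntegerVector& genome,
                              const IntegerVector& read) {
  const int L = genome.size(), k = read.size();
  if (k == 0 || L < k) return IntegerVector(0);
  IntegerVector out(L - k + 1);
  for (int s = 0; s <= L - k; ++s) {
    int d = 0;
    for (int i = 0; i < k; ++i) {
      const int a = genome[s + i], b = read[i];
      if (a != b || a == 0) ++d;
    }
    out[s] = d;
  }
  return out;
}
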