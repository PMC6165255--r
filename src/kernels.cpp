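#include <Rcpp.h>
using namespace Rcpp;

// Histogram-intersection Gram matrix: G(i, j) = sum_k min(A(i, k), B(j, k)).
// [[Rcpp::export]]
NumericMatrix cpp_intersection_gram(const NumericMatrix& A,
                                    const NumericMatrix& B) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("histogram lengths differ");
  NumericMatrix G(na, nb);
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < na; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k)
        s += std::min(A(i, k), B(j, k));
      G(i, j) = s;
    }
  return G;
}
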