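// Batched symmetric 3x3 eigendecomposition for per-voxel tensor analysis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// tens: 6 x N matrix, rows in (xx, xy, xz, yy, yz, zz) order.
// Returns values (3 x N, ascending) and vectors (9 x N, columns of the
// eigenvector matrix stacked v1|v2|v3 matching the value order).
// [[Rcpp::export(name = ".eigen3x3_batch")]]
List eigen3x3_batch(const NumericMatrix& tens) {
  if (tens.nrow() != 6) stop("expected a 6 x N tensor matrix");
  const int n = tens.ncol();
  NumericMatrix values(3, n), vectors(9, n);
  arma::mat33 A;
  arma::vec3 eval;
  arma::mat33 evec;
  for (int i = 0; i < n; ++i) {
    const double xx = tens(0, i), xy = tens(1, i), xz = tens(2, i);
    const double yy = tens(3, i), yz = tens(4, i), zz = tens(5, i);
    A(0, 0) = xx; A(0, 1) = xy; A(0, 2) = xz;
    A(1, 0) = xy; A(1, 1) = yy; A(1, 2) = yz;
    A(2, 0) = xz; A(2, 1) = yz; A(2, 2) = zz;
    if (!arma::eig_sym(eval, evec, A)) {
      for (int k = 0; k < 3; ++k) values(k, i) = NA_REAL;
      for (int k = 0; k < 9; ++k) vectors(k, i) = NA_REAL;
      continue;
    }
    for (int k = 0; k < 3; ++k) values(k, i) = eval(k);
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) vectors(3 * c + r, i) = evec(r, c);
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}
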