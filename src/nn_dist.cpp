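#include <Rcpp.h>
using namespace Rcpp;

// Directed nearest-neighbour Euclidean distances between two point sets
// (surface voxel centres in mm). Exact per-axis arithmetic, so results
// agree with a direct per-pair computation to double precision.
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  const double *az = &A(0, 0), *ay = &A(0, 1), *ax = &A(0, 2);
  const double *bz = &B(0, 0), *by = &B(0, 1), *bx = &B(0, 2);
  for (int i = 0; i < n; ++i) {
    const double zi = az[i], yi = ay[i], xi = ax[i];
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dz = zi - bz[j];
      const double dy = yi - by[j];
      const double dx = xi - bx[j];
      const double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
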