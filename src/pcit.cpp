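#include <Rcpp.h>
using namespace Rcpp;

// PCIT trio elimination on a correlation matrix.
//
// For every unordered trio (x, y, z): first-order partial correlations
//   r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))
// and the two rotations. The trio tolerance is the mean of the absolute
// ratios |partial / direct| over the three pairs (ratios with
// |direct| < 1e-12 are skipped; a trio with no valid ratio is skipped).
// Edge (x, y) is eliminated if, within some trio, both
// |r_xy| <= |eps * r_xz| and |r_xy| <= |eps * r_yz| (ties eliminate).
//
// Returns a logical keep matrix (TRUE = edge survives), diagonal FALSE.
// [[Rcpp::export(name = ".pcit_keep_cpp")]]
LogicalMatrix pcit_keep_cpp(NumericMatrix corr) {
  const int n = corr.nrow();
  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) keep(i, j) = (i != j);
  if (n < 3) return keep;

  const double tiny = 1e-12;
  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = corr(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = corr(x, z);
        const double ryz = corr(y, z);
        // partials; guard degenerate denominators
        const double den_xy = std::sqrt((1.0 - rxz * rxz) *
                                        (1.0 - ryz * ryz));
        const double den_xz = std::sqrt((1.0 - rxy * rxy) *
                                        (1.0 - ryz * ryz));
        const double den_yz = std::sqrt((1.0 - rxy * rxy) *
                                        (1.0 - rxz * rxz));
        double sum = 0.0; int cnt = 0;
        if (std::fabs(rxy) >= tiny && den_xy > tiny) {
          sum += std::fabs(((rxy - rxz * ryz) / den_xy) / rxy); ++cnt;
        }
        if (std::fabs(rxz) >= tiny && den_xz > tiny) {
          sum += std::fabs(((rxz - rxy * ryz) / den_xz) / rxz); ++cnt;
        }
        if (std::fabs(ryz) >= tiny && den_yz > tiny) {
          sum += std::fabs(((ryz - rxy * rxz) / den_yz) / ryz); ++cnt;
        }
        if (cnt == 0) continue;
        const double eps = sum / cnt;
        // edge x-y against z
        if (std::fabs(rxy) <= std::fabs(eps * rxz) &&
            std::fabs(rxy) <= std::fabs(eps * ryz)) {
          keep(x, y) = keep(y, x) = false;
        }
        // edge x-z against y
        if (std::fabs(rxz) <= std::fabs(eps * rxy) &&
            std::fabs(rxz) <= std::fabs(eps * ryz)) {
          keep(x, z) = keep(z, x) = false;
        }
        // edge y-z against x
        if (std::fabs(ryz) <= std::fabs(eps * rxy) &&
            std::fabs(ryz) <= std::fabs(eps * rxz)) {
          keep(y, z) = keep(z, y) = false;
        }
      }
    }
  }
  return keep;
}
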