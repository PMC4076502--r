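#include <Rcpp.h>
using namespace Rcpp;

// Condensed joint pmf for equal arm sizes (R cases, R controls).
//
// With r_x = r_y = R the lattice coordinates z1 = R(X3 - Y3) and
// z2 = R(X2 - Y2) are multiples of R, so the support condenses to the
// (2R+1) x (2R+1) grid of differences d1 = X3 - Y3, d2 = X2 - Y2. The mass
// at (d1, d2) is the cross-correlation of the two trinomial triangles:
//   m(d1, d2) = sum_{x2, x3} fX(x2, x3) * fY(x2 - d2, x3 - d1)
// restricted to 0 <= x2 + x3 <= R and 0 <= (x2-d2) + (x3-d1) <= R.
//
// lfx, lfy: (R+1) x (R+1) matrices of log trinomial masses, row = count of
// Aa (x2), col = count of aa (x3); entries with x2 + x3 > R are ignored.
// Invalid/zero-probability cells carry -Inf and contribute zero mass.
// symmetric: when the two probability triples coincide, m(-d1, -d2) =
// m(d1, d2), and only half the grid is evaluated.
//
// Masses are accumulated in probability space: log masses are
// exponentiated once up front. Cells whose every term is below the double
// underflow threshold flush to zero; such cells cannot perturb a p-value
// at double precision.
// [[Rcpp::export]]
NumericMatrix condensed_pmf_cpp(int R, NumericMatrix lfx, NumericMatrix lfy,
                                bool symmetric) {
  const int side = 2 * R + 1;
  const int n1 = R + 1;
  NumericMatrix out(side, side); // row: d2 + R, col: d1 + R
  // flat col-major copies, exponentiated once: ex[x2 + n1 * x3]
  std::vector<double> ex(n1 * n1, 0.0), ey(n1 * n1, 0.0);
  for (int x3 = 0; x3 <= R; ++x3) {
    for (int x2 = 0; x2 <= R - x3; ++x2) {
      ex[x2 + n1 * x3] = std::exp(lfx(x2, x3));
      ey[x2 + n1 * x3] = std::exp(lfy(x2, x3));
    }
  }
  for (int d1 = -R; d1 <= R; ++d1) {
    if (symmetric && d1 > 0) break;
    const int d2max = (symmetric && d1 == 0) ? 0 : R;
    const int x3lo = std::max(0, d1);
    const int x3hi = std::min(R, R + d1);
    for (int d2 = -R; d2 <= d2max; ++d2) {
      double s = 0.0;
      const int x2lo = std::max(0, d2);
      for (int x3 = x3lo; x3 <= x3hi; ++x3) {
        // x2 + x3 <= R and (x2 - d2) + (x3 - d1) <= R
        const int x2hi = std::min(R - x3, R + d2 + d1 - x3);
        const double *px = &ex[n1 * x3] + x2lo;
        const double *py = &ey[n1 * (x3 - d1) - d2] + x2lo;
        for (int x2 = x2lo; x2 <= x2hi; ++x2) s += *px++ * *py++;
      }
      out(d2 + R, d1 + R) = s;
      if (symmetric) out(R - d2, R - d1) = s;
    }
  }
  return out;
}
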