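// Two-layer diffusion kernel in Hankel (s) and temporal-frequency (omega)
// space, evaluated at the medium surface (z = 0).
//
// The fluence of a point source at depth z0 inside the top layer (thickness
// l, extrapolated boundary at z = -zb) of a two-layer medium with a
// semi-infinite bottom layer satisfies, after a 2-D spatial Fourier (Hankel)
// transform and a temporal Fourier transform,
//
//   phi_k'' - alpha_k^2 phi_k = -delta(z - z0) / D1,
//   alpha_k^2 = s^2 + (mua_k + i omega / v_k) / D_k,
//
// with phi(-zb) = 0, continuity of phi and of D dphi/dz at z = l, and
// phi -> 0 as z -> infinity. The surface value is
//
//   phi(s, 0, omega) = sinh(a1 zb) / (D1 a1)
//       * [D1 a1 cosh(a1 (l - z0)) + D2 a2 sinh(a1 (l - z0))]
//       / [D1 a1 cosh(a1 (l + zb)) + D2 a2 sinh(a1 (l + zb))],
//
// implemented in an overflow-safe form with only decaying exponentials.
// The caller supplies quadrature coefficients coef_j = w_j s_j J0(s_j rho)
// / (2 pi) so that the returned vector is the inverse Hankel transform
// phi(rho, z = 0, omega) on the requested frequency grid.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".tl_kernel_cpp")]]
ComplexVector tl_kernel_cpp(NumericVector s, NumericVector coef,
                            NumericVector omega,
                            double mua1, double D1, double v1,
                            double mua2, double D2, double v2,
                            double l, double z0, double zb) {
  const int ns = s.size(), nw = omega.size();
  std::vector<double> s2(ns);
  for (int j = 0; j < ns; ++j) s2[j] = s[j] * s[j];

  ComplexVector out(nw);
  const std::complex<double> one(1.0, 0.0);
  for (int k = 0; k < nw; ++k) {
    const std::complex<double> q1(mua1 / D1, omega[k] / (v1 * D1));
    const std::complex<double> q2(mua2 / D2, omega[k] / (v2 * D2));
    std::complex<double> acc(0.0, 0.0);
    for (int j = 0; j < ns; ++j) {
      const std::complex<double> a1 = std::sqrt(s2[j] + q1);
      const std::complex<double> a2 = std::sqrt(s2[j] + q2);
      const std::complex<double> D1a1 = D1 * a1;
      const std::complex<double> D2a2 = D2 * a2;
      const std::complex<double> ez0 = std::exp(-a1 * z0);
      const std::complex<double> E1 = std::exp(-2.0 * a1 * (l - z0));
      const std::complex<double> Ezb = std::exp(-2.0 * a1 * zb);
      const std::complex<double> E2 = E1 * ez0 * ez0 * Ezb; // e^{-2 a1 (l+zb)}
      const std::complex<double> num = D1a1 * (one + E1) + D2a2 * (one - E1);
      const std::complex<double> den = D1a1 * (one + E2) + D2a2 * (one - E2);
      acc += coef[j] * ((one - Ezb) * ez0 / (2.0 * D1a1) * (num / den));
    }
    out[k] = Rcomplex{acc.real(), acc.imag()};
  }
  return out;
}
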