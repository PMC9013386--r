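#include <Rcpp.h>
using namespace Rcpp;

// Magnetostatic field of a set of point magnetic charges (A*m) and
// z-oriented point dipoles (A*m^2), evaluated at arbitrary points.
// All coordinates in metres, fields returned in A/m.
//
// H_charge(p)  = q/(4*pi) * (p - s)/|p - s|^3
// H_dipole(p)  = 1/(4*pi*r^3) * (3*(m.rhat)*rhat - m),  m = (0, 0, mz)

// [[Rcpp::export]]
NumericMatrix cpp_field_at(NumericMatrix points,
                           NumericMatrix charge_pos, NumericVector charge_q,
                           NumericMatrix dipole_pos, NumericVector dipole_mz) {
  const int np = points.nrow();
  const int nc = charge_pos.nrow();
  const int nd = dipole_pos.nrow();
  const double inv4pi = 1.0 / (4.0 * M_PI);
  NumericMatrix H(np, 3);

  for (int i = 0; i < np; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double hx = 0.0, hy = 0.0, hz = 0.0;
    for (int j = 0; j < nc; ++j) {
      const double dx = px - charge_pos(j, 0);
      const double dy = py - charge_pos(j, 1);
      const double dz = pz - charge_pos(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double r = std::sqrt(r2);
      const double f = charge_q[j] * inv4pi / (r2 * r);
      hx += f * dx; hy += f * dy; hz += f * dz;
    }
    for (int j = 0; j < nd; ++j) {
      const double dx = px - dipole_pos(j, 0);
      const double dy = py - dipole_pos(j, 1);
      const double dz = pz - dipole_pos(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double r = std::sqrt(r2);
      const double mz = dipole_mz[j];
      // 3*(m.r)*r/r^5 - m/r^3, with m = (0,0,mz)
      const double f = 3.0 * mz * dz * inv4pi / (r2 * r2 * r);
      hx += f * dx;
      hy += f * dy;
      hz += f * dz - mz * inv4pi / (r2 * r);
    }
    H(i, 0) = hx; H(i, 1) = hy; H(i, 2) = hz;
  }
  return H;
}

// Squared magnitude of total field (stray + uniform external) at points.
// [[Rcpp::export]]
NumericVector cpp_h2_at(NumericMatrix points,
                        NumericMatrix charge_pos, NumericVector charge_q,
                        NumericMatrix dipole_pos, NumericVector dipole_mz,
                        NumericVector h_ext) {
  NumericMatrix H = cpp_field_at(points, charge_pos, charge_q,
                                 dipole_pos, dipole_mz);
  const int np = points.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double hx = H(i, 0) + h_ext[0];
    const double hy = H(i, 1) + h_ext[1];
    const double hz = H(i, 2) + h_ext[2];
    out[i] = hx * hx + hy * hy + hz * hz;
  }
  return out;
}
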