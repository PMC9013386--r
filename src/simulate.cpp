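#include <Rcpp.h>
using namespace Rcpp;

static const double MU0C = 4.0 * M_PI * 1e-7;
static const double KBC = 1.380649e-23;

// |H_total|^2 at a point (metres) for the film magnetized along
// (cphi, s*sphi) in-plane (precomputed per-element charges qx, qy) plus a
// constant vertical dipole sheet.
static inline double h2_point(double px, double py, double pz,
                              const double* cx, const double* cy,
                              const double* cz, const double* qx,
                              const double* qy, int nc,
                              const double* dx_, const double* dy_,
                              const double* dz_, const double* mz, int nd,
                              double cphi, double ssphi,
                              double hex, double hey, double hez) {
  const double inv4pi = 1.0 / (4.0 * M_PI);
  double hx = hex, hy = hey, hz = hez;
  for (int j = 0; j < nc; ++j) {
    const double q = cphi * qx[j] + ssphi * qy[j];
    const double rx = px - cx[j], ry = py - cy[j], rz = pz - cz[j];
    const double r2 = rx * rx + ry * ry + rz * rz;
    const double f = q * inv4pi / (r2 * std::sqrt(r2));
    hx += f * rx; hy += f * ry; hz += f * rz;
  }
  for (int j = 0; j < nd; ++j) {
    const double rx = px - dx_[j], ry = py - dy_[j], rz = pz - dz_[j];
    const double r2 = rx * rx + ry * ry + rz * rz;
    const double r = std::sqrt(r2);
    const double f = 3.0 * mz[j] * rz * inv4pi / (r2 * r2 * r);
    hx += f * rx; hy += f * ry;
    hz += f * rz - mz[j] * inv4pi / (r2 * r);
  }
  return hx * hx + hy * hy + hz * hz;
}

// Overdamped forward-difference integrator with a displacement cap per
// substep.  Positions in micrometres; returns (nsteps+1) x n x 2 array.
// [[Rcpp::export]]
NumericVector cpp_simulate(NumericMatrix pos0, NumericVector z_um,
                           NumericVector radius_um, NumericVector chi,
                           NumericVector vol_m3,
                           NumericMatrix charge_pos, NumericVector qx,
                           NumericVector qy, NumericMatrix dipole_pos,
                           NumericVector mz,
                           double hin_am, double hv_am, double freq,
                           double phase0, double sense_sign, double chi_f,
                           double eta, double dt, int nsteps,
                           double cap_um, double grad_h_um,
                           bool thermal, double temp_k,
                           double bounds_lo_x, double bounds_lo_y,
                           double bounds_hi_x, double bounds_hi_y,
                           bool use_bounds) {
  const int n = pos0.nrow();
  const int nc = charge_pos.nrow();
  const int nd = dipole_pos.nrow();
  std::vector<double> cx(nc), cy(nc), cz(nc);
  for (int j = 0; j < nc; ++j) {
    cx[j] = charge_pos(j, 0); cy[j] = charge_pos(j, 1);
    cz[j] = charge_pos(j, 2);
  }
  std::vector<double> dx_(nd), dy_(nd), dz_(nd);
  for (int j = 0; j < nd; ++j) {
    dx_[j] = dipole_pos(j, 0); dy_[j] = dipole_pos(j, 1);
    dz_[j] = dipole_pos(j, 2);
  }
  std::vector<double> x(n), y(n), drag(n), mpref(n), diff_um2(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    drag[i] = 6.0 * M_PI * eta * radius_um[i] * 1e-6;       // N s / m
    const double rm = radius_um[i] * 1e-6;
    mpref[i] = 4.0 * M_PI * rm * rm * rm * chi[i] / 3.0;    // m^3
    diff_um2[i] = KBC * temp_k / drag[i] * 1e12;            // um^2/s
  }
  NumericVector out((nsteps + 1) * n * 2);
  out.attr("dim") = IntegerVector::create(nsteps + 1, n, 2);
  for (int i = 0; i < n; ++i) {
    out[0 + i * (nsteps + 1)] = x[i];
    out[0 + i * (nsteps + 1) + n * (nsteps + 1)] = y[i];
  }
  double t = 0.0;
  const double hstep = grad_h_um;
  std::vector<double> vx(n), vy(n), pvx(n, 0.0), pvy(n, 0.0);
  bool havePrev = false;
  double localCap = cap_um;

  for (int k = 1; k <= nsteps; ++k) {
    double remaining = dt;
    havePrev = false;
    localCap = cap_um;
    while (remaining > 1e-12) {
      const double phi = 2.0 * M_PI * freq * t + phase0;
      const double cphi = std::cos(phi), ssphi = sense_sign * std::sin(phi);
      const double hex = hin_am * cphi, hey = hin_am * ssphi, hez = hv_am;
      double vmax = 1e-12;
      for (int i = 0; i < n; ++i) {
        double fx = 0.0, fy = 0.0;
        if (nc > 0 || nd > 0) {
          const double pz = z_um[i] * 1e-6;
          const double upref = -0.5 * MU0C * vol_m3[i] * (chi[i] - chi_f);
          const double uxp = upref * h2_point((x[i] + hstep) * 1e-6, y[i] * 1e-6, pz, cx.data(), cy.data(), cz.data(), qx.begin(), qy.begin(), nc, dx_.data(), dy_.data(), dz_.data(), mz.begin(), nd, cphi, ssphi, hex, hey, hez);
          const double uxm = upref * h2_point((x[i] - hstep) * 1e-6, y[i] * 1e-6, pz, cx.data(), cy.data(), cz.data(), qx.begin(), qy.begin(), nc, dx_.data(), dy_.data(), dz_.data(), mz.begin(), nd, cphi, ssphi, hex, hey, hez);
          const double uyp = upref * h2_point(x[i] * 1e-6, (y[i] + hstep) * 1e-6, pz, cx.data(), cy.data(), cz.data(), qx.begin(), qy.begin(), nc, dx_.data(), dy_.data(), dz_.data(), mz.begin(), nd, cphi, ssphi, hex, hey, hez);
          const double uym = upref * h2_point(x[i] * 1e-6, (y[i] - hstep) * 1e-6, pz, cx.data(), cy.data(), cz.data(), qx.begin(), qy.begin(), nc, dx_.data(), dy_.data(), dz_.data(), mz.begin(), nd, cphi, ssphi, hex, hey, hez);
          fx = -(uxp - uxm) / (2.0 * hstep * 1e-6);
          fy = -(uyp - uym) / (2.0 * hstep * 1e-6);
        }
        vx[i] = fx / drag[i] * 1e6;   // um/s
        vy[i] = fy / drag[i] * 1e6;
      }
      if (n > 1) {
        for (int i = 0; i < n - 1; ++i) {
          for (int j = i + 1; j < n; ++j) {
            const double rx = (x[i] - x[j]) * 1e-6;
            const double ry = (y[i] - y[j]) * 1e-6;
            const double r2 = rx * rx + ry * ry;
            if (r2 < 1e-30) continue;
            const double rmag = std::sqrt(r2);
            // moments along the drive field
            const double m1x = mpref[i] * hex, m1y = mpref[i] * hey,
              m1z = mpref[i] * hez;
            const double m2x = mpref[j] * hex, m2y = mpref[j] * hey,
              m2z = mpref[j] * hez;
            const double m1r = m1x * rx + m1y * ry;
            const double m2r = m2x * rx + m2y * ry;
            const double m12 = m1x * m2x + m1y * m2y + m1z * m2z;
            const double pref = 3.0 * MU0C /
              (4.0 * M_PI * rmag * rmag * rmag * rmag * rmag);
            const double fpx = pref * (m1r * m2x + m2r * m1x + m12 * rx -
                                       5.0 * m1r * m2r * rx / r2);
            const double fpy = pref * (m1r * m2y + m2r * m1y + m12 * ry -
                                       5.0 * m1r * m2r * ry / r2);
            vx[i] += fpx / drag[i] * 1e6; vy[i] += fpy / drag[i] * 1e6;
            vx[j] -= fpx / drag[j] * 1e6; vy[j] -= fpy / drag[j] * 1e6;
          }
        }
      }
      for (int i = 0; i < n; ++i) {
        const double v = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
        if (v > vmax) vmax = v;
      }
      if (!thermal && vmax * remaining < 0.002) { t += remaining; break; }
      if (havePrev) {
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += vx[i] * pvx[i] + vy[i] * pvy[i];
        if (dot < 0.0) localCap = std::max(localCap / 2.0, 0.002);
        else localCap = std::min(localCap * 1.5, cap_um);
      }
      for (int i = 0; i < n; ++i) { pvx[i] = vx[i]; pvy[i] = vy[i]; }
      havePrev = true;
      const double dt_sub = std::min(remaining, localCap / vmax);
      for (int i = 0; i < n; ++i) {
        x[i] += vx[i] * dt_sub; y[i] += vy[i] * dt_sub;
        if (thermal) {
          const double sd = std::sqrt(2.0 * diff_um2[i] * dt_sub);
          x[i] += R::norm_rand() * sd;
          y[i] += R::norm_rand() * sd;
        }
        if (use_bounds) {
          if (x[i] < bounds_lo_x + radius_um[i]) x[i] = 2.0 * (bounds_lo_x + radius_um[i]) - x[i];
          if (x[i] > bounds_hi_x - radius_um[i]) x[i] = 2.0 * (bounds_hi_x - radius_um[i]) - x[i];
          if (y[i] < bounds_lo_y + radius_um[i]) y[i] = 2.0 * (bounds_lo_y + radius_um[i]) - y[i];
          if (y[i] > bounds_hi_y - radius_um[i]) y[i] = 2.0 * (bounds_hi_y - radius_um[i]) - y[i];
        }
      }
      if (n > 1) {  // hard-sphere: minimal symmetric projection
        for (int i = 0; i < n - 1; ++i) {
          for (int j = i + 1; j < n; ++j) {
            const double ddx = x[i] - x[j], ddy = y[i] - y[j];
            const double d = std::sqrt(ddx * ddx + ddy * ddy);
            const double dmin = radius_um[i] + radius_um[j];
            if (d < dmin && d > 0) {
              const double push = (dmin - d) / 2.0;
              x[i] += push * ddx / d; y[i] += push * ddy / d;
              x[j] -= push * ddx / d; y[j] -= push * ddy / d;
            }
          }
        }
      }
      t += dt_sub;
      remaining -= dt_sub;
    }
    t = dt * k;   // guard against drift
    for (int i = 0; i < n; ++i) {
      out[k + i * (nsteps + 1)] = x[i];
      out[k + i * (nsteps + 1) + n * (nsteps + 1)] = y[i];
    }
  }
  return out;
}
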