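// Force-field kernel: harmonic bonds/angles, cosine torsions, purely
// repulsive truncated-and-shifted excluded volume. Coordinates in Angstrom,
// energies in kJ/mol, angle terms in radians. Index matrices are 1-based
// (converted here); pair/term lists are prepared on the R side.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double COINCIDENT_R = 1e-9;
static const double COINCIDENT_PENALTY = 1e10;

static inline void getv(const NumericMatrix& x, int i, double* v) {
  v[0] = x(i, 0); v[1] = x(i, 1); v[2] = x(i, 2);
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Dihedral about b2 for bond vectors b1 = r2-r1, b2 = r3-r2, b3 = r4-r3.
static double dihedral(const double* b1, const double* b2, const double* b3) {
  double n1[3], n2[3], m[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double nb2 = norm3(b2);
  if (nb2 < COINCIDENT_R) return 0.0;
  double bu[3] = { b2[0] / nb2, b2[1] / nb2, b2[2] / nb2 };
  cross3(n1, n2, m);
  double y = dot3(m, bu);
  double x = dot3(n1, n2);
  return std::atan2(y, x);
}

// [[Rcpp::export]]
NumericVector cg_energy_components(const NumericMatrix& xyz,
                                   const IntegerMatrix& bonds,
                                   const NumericVector& bond_r0,
                                   const NumericVector& bond_k,
                                   const IntegerMatrix& angles,
                                   const NumericVector& ang_th0,
                                   const NumericVector& ang_k,
                                   const IntegerMatrix& tors,
                                   const NumericVector& tor_phi0,
                                   const NumericVector& tor_p,
                                   const NumericVector& tor_k,
                                   const IntegerMatrix& pairs,
                                   const NumericVector& pr_sig,
                                   const NumericVector& pr_eps,
                                   const NumericVector& pr_cut) {
  double e_bond = 0.0, e_angle = 0.0, e_tor = 0.0, e_ev = 0.0;
  double a[3], b[3], c[3], d[3], u[3], v[3], w[3];

  for (int t = 0; t < bonds.nrow(); ++t) {
    getv(xyz, bonds(t, 0) - 1, a);
    getv(xyz, bonds(t, 1) - 1, b);
    u[0] = b[0] - a[0]; u[1] = b[1] - a[1]; u[2] = b[2] - a[2];
    double dr = norm3(u) - bond_r0[t];
    e_bond += 0.5 * bond_k[t] * dr * dr;
  }

  for (int t = 0; t < angles.nrow(); ++t) {
    getv(xyz, angles(t, 0) - 1, a);
    getv(xyz, angles(t, 1) - 1, b);
    getv(xyz, angles(t, 2) - 1, c);
    u[0] = a[0] - b[0]; u[1] = a[1] - b[1]; u[2] = a[2] - b[2];
    v[0] = c[0] - b[0]; v[1] = c[1] - b[1]; v[2] = c[2] - b[2];
    double nu = norm3(u), nv = norm3(v);
    if (nu < COINCIDENT_R || nv < COINCIDENT_R) { e_angle += COINCIDENT_PENALTY; continue; }
    double ct = dot3(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double dth = std::acos(ct) - ang_th0[t];
    e_angle += 0.5 * ang_k[t] * dth * dth;
  }

  for (int t = 0; t < tors.nrow(); ++t) {
    getv(xyz, tors(t, 0) - 1, a);
    getv(xyz, tors(t, 1) - 1, b);
    getv(xyz, tors(t, 2) - 1, c);
    getv(xyz, tors(t, 3) - 1, d);
    u[0] = b[0] - a[0]; u[1] = b[1] - a[1]; u[2] = b[2] - a[2];
    v[0] = c[0] - b[0]; v[1] = c[1] - b[1]; v[2] = c[2] - b[2];
    w[0] = d[0] - c[0]; w[1] = d[1] - c[1]; w[2] = d[2] - c[2];
    double phi = dihedral(u, v, w);
    e_tor += tor_k[t] * (1.0 + std::cos(tor_p[t] * phi - tor_phi0[t]));
  }

  for (int t = 0; t < pairs.nrow(); ++t) {
    getv(xyz, pairs(t, 0) - 1, a);
    getv(xyz, pairs(t, 1) - 1, b);
    u[0] = b[0] - a[0]; u[1] = b[1] - a[1]; u[2] = b[2] - a[2];
    double r = norm3(u);
    double cut = pr_cut[t];
    if (r >= cut) continue;
    if (r < COINCIDENT_R) { e_ev += COINCIDENT_PENALTY; continue; }
    double sr = pr_sig[t] / r, sc = pr_sig[t] / cut;
    double e = pr_eps[t] * (std::pow(sr, 12) - std::pow(sc, 12));
    if (e > COINCIDENT_PENALTY) e = COINCIDENT_PENALTY;
    e_ev += e;
  }

  return NumericVector::create(_["bond"] = e_bond, _["angle"] = e_angle,
                               _["torsion"] = e_tor, _["excluded_volume"] = e_ev);
}

// [[Rcpp::export]]
NumericMatrix cg_gradient(const NumericMatrix& xyz,
                          const IntegerMatrix& bonds,
                          const NumericVector& bond_r0,
                          const NumericVector& bond_k,
                          const IntegerMatrix& angles,
                          const NumericVector& ang_th0,
                          const NumericVector& ang_k,
                          const IntegerMatrix& tors,
                          const NumericVector& tor_phi0,
                          const NumericVector& tor_p,
                          const NumericVector& tor_k,
                          const IntegerMatrix& pairs,
                          const NumericVector& pr_sig,
                          const NumericVector& pr_eps,
                          const NumericVector& pr_cut) {
  int n = xyz.nrow();
  NumericMatrix g(n, 3);
  double a[3], b[3], c[3], d[3], u[3], v[3], w[3];

  for (int t = 0; t < bonds.nrow(); ++t) {
    int i = bonds(t, 0) - 1, j = bonds(t, 1) - 1;
    getv(xyz, i, a); getv(xyz, j, b);
    u[0] = b[0] - a[0]; u[1] = b[1] - a[1]; u[2] = b[2] - a[2];
    double r = norm3(u);
    if (r < COINCIDENT_R) continue;
    double f = bond_k[t] * (r - bond_r0[t]) / r;
    for (int q = 0; q < 3; ++q) {
      g(j, q) += f * u[q];
      g(i, q) -= f * u[q];
    }
  }

  for (int t = 0; t < angles.nrow(); ++t) {
    int i = angles(t, 0) - 1, j = angles(t, 1) - 1, k = angles(t, 2) - 1;
    getv(xyz, i, a); getv(xyz, j, b); getv(xyz, k, c);
    u[0] = a[0] - b[0]; u[1] = a[1] - b[1]; u[2] = a[2] - b[2];
    v[0] = c[0] - b[0]; v[1] = c[1] - b[1]; v[2] = c[2] - b[2];
    double nu = norm3(u), nv = norm3(v);
    if (nu < COINCIDENT_R || nv < COINCIDENT_R) continue;
    double ct = dot3(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) continue; // gradient of theta undefined at 0/pi; dE/dtheta -> 0 at minima there
    double theta = std::acos(ct);
    double dEdth = ang_k[t] * (theta - ang_th0[t]);
    for (int q = 0; q < 3; ++q) {
      double uh = u[q] / nu, vh = v[q] / nv;
      double gi = (ct * uh - vh) / (nu * st);
      double gk = (ct * vh - uh) / (nv * st);
      g(i, q) += dEdth * gi;
      g(k, q) += dEdth * gk;
      g(j, q) -= dEdth * (gi + gk);
    }
  }

  for (int t = 0; t < tors.nrow(); ++t) {
    int i1 = tors(t, 0) - 1, i2 = tors(t, 1) - 1, i3 = tors(t, 2) - 1, i4 = tors(t, 3) - 1;
    getv(xyz, i1, a); getv(xyz, i2, b); getv(xyz, i3, c); getv(xyz, i4, d);
    u[0] = b[0] - a[0]; u[1] = b[1] - a[1]; u[2] = b[2] - a[2]; // b1
    v[0] = c[0] - b[0]; v[1] = c[1] - b[1]; v[2] = c[2] - b[2]; // b2
    w[0] = d[0] - c[0]; w[1] = d[1] - c[1]; w[2] = d[2] - c[2]; // b3
    double n1[3], n2[3];
    cross3(u, v, n1);
    cross3(v, w, n2);
    double nn1 = dot3(n1, n1), nn2 = dot3(n2, n2), nb2 = norm3(v);
    if (nn1 < 1e-16 || nn2 < 1e-16 || nb2 < COINCIDENT_R) continue;
    double phi = dihedral(u, v, w);
    double dEdphi = -tor_k[t] * tor_p[t] * std::sin(tor_p[t] * phi - tor_phi0[t]);
    double p1[3], p4[3];
    for (int q = 0; q < 3; ++q) {
      p1[q] = -nb2 / nn1 * n1[q];
      p4[q] = nb2 / nn2 * n2[q];
    }
    double tv = dot3(u, v) / (nb2 * nb2);
    double sv = dot3(w, v) / (nb2 * nb2);
    for (int q = 0; q < 3; ++q) {
      double g2 = -(1.0 + tv) * p1[q] + sv * p4[q];
      double g3 = tv * p1[q] - (1.0 + sv) * p4[q];
      g(i1, q) += dEdphi * p1[q];
      g(i2, q) += dEdphi * g2;
      g(i3, q) += dEdphi * g3;
      g(i4, q) += dEdphi * p4[q];
    }
  }

  for (int t = 0; t < pairs.nrow(); ++t) {
    int i = pairs(t, 0) - 1, j = pairs(t, 1) - 1;
    getv(xyz, i, a); getv(xyz, j, b);
    u[0] = b[0] - a[0]; u[1] = b[1] - a[1]; u[2] = b[2] - a[2];
    double r = norm3(u);
    if (r >= pr_cut[t] || r < COINCIDENT_R) continue;
    double sr = pr_sig[t] / r;
    double dEdr = -12.0 * pr_eps[t] * std::pow(sr, 12) / r;
    if (dEdr < -1e12) dEdr = -1e12;
    double f = dEdr / r;
    for (int q = 0; q < 3; ++q) {
      g(j, q) += f * u[q];
      g(i, q) -= f * u[q];
    }
  }

  return g;
}
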