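// Numerical kernels: restraint enumeration, restraint/stereochemical/X-ray
// energies with analytic gradients, direct-summation structure factors, and
// the velocity-Verlet integrator used by the annealing protocol.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <complex>

using namespace Rcpp;

static const double R2D = 57.29577951308232;   // degrees per radian
static const double TWOPI = 6.283185307179586;

// ---------------------------------------------------------------------------
// Restraint enumeration
// ---------------------------------------------------------------------------

static inline double dist3(const NumericMatrix& x, int i, int j) {
  double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1),
         dz = x(i, 2) - x(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline double angle_ijk(const NumericMatrix& x, int v, int t1, int t2) {
  double ux = x(t1, 0) - x(v, 0), uy = x(t1, 1) - x(v, 1),
         uz = x(t1, 2) - x(v, 2);
  double wx = x(t2, 0) - x(v, 0), wy = x(t2, 1) - x(v, 1),
         wz = x(t2, 2) - x(v, 2);
  double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
  double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
  if (nu <= 0 || nw <= 0) return -1.0;
  double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c) * R2D;
}

// rows0: 0-based rows of the reference eligible for restraints, in serial
// order.  Returns admissible triplets (1-based row indices) with the vertex
// angle measured in the reference.
// [[Rcpp::export]]
List cpp_enumerate_dan(NumericMatrix xyz, IntegerVector rows0,
                       IntegerVector serial, IntegerVector chain,
                       IntegerVector resno, double cutoff, int max_sep,
                       double angle_min, double angle_max, bool directional) {
  int n = rows0.size();
  std::vector<int> vv, v1, v2;
  std::vector<double> th;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      for (int c = b + 1; c < n; ++c) {
        int i = rows0[a], j = rows0[b], k = rows0[c];
        if (chain[i] != chain[j] || chain[j] != chain[k]) continue;
        // candidate vertices; tails keep serial order (i < j < k already)
        int nvert = directional ? 1 : 3;
        for (int w = 0; w < nvert; ++w) {
          int v, t1, t2;
          if (w == 0)      { v = i; t1 = j; t2 = k; }
          else if (w == 1) { v = j; t1 = i; t2 = k; }
          else             { v = k; t1 = i; t2 = j; }
          if (std::abs(resno[v] - resno[t1]) > max_sep) continue;
          if (std::abs(resno[v] - resno[t2]) > max_sep) continue;
          if (dist3(xyz, v, t1) > cutoff) continue;
          if (dist3(xyz, v, t2) > cutoff) continue;
          double ang = angle_ijk(xyz, v, t1, t2);
          if (ang < angle_min || ang > angle_max) continue;
          vv.push_back(v + 1); v1.push_back(t1 + 1); v2.push_back(t2 + 1);
          th.push_back(ang);
        }
      }
    }
  }
  return List::create(_["vertex"] = wrap(vv), _["tail1"] = wrap(v1),
                      _["tail2"] = wrap(v2), _["theta"] = wrap(th));
}

// [[Rcpp::export]]
List cpp_enumerate_den(NumericMatrix xyz, IntegerVector rows0,
                       IntegerVector chain, IntegerVector resno,
                       double cutoff, int max_sep) {
  int n = rows0.size();
  std::vector<int> va, vb;
  std::vector<double> vd;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int i = rows0[a], j = rows0[b];
      if (chain[i] != chain[j]) continue;
      if (std::abs(resno[i] - resno[j]) > max_sep) continue;
      double d = dist3(xyz, i, j);
      if (d > cutoff || d <= 0) continue;
      va.push_back(i + 1); vb.push_back(j + 1); vd.push_back(d);
    }
  }
  return List::create(_["a"] = wrap(va), _["b"] = wrap(vb),
                      _["d"] = wrap(vd));
}

// ---------------------------------------------------------------------------
// Harmonic restraint energies (gradients accumulated into `grad`)
// ---------------------------------------------------------------------------

static int den_accumulate(const NumericMatrix& xyz, const IntegerVector& ia,
                          const IntegerVector& ib, const NumericVector& d_eq,
                          double k, double w, double& energy,
                          NumericMatrix& grad) {
  int ndeg = 0;
  for (int r = 0; r < ia.size(); ++r) {
    int i = ia[r], j = ib[r];
    double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
           dz = xyz(i, 2) - xyz(j, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d <= 1e-12) { ++ndeg; continue; }
    double dev = d - d_eq[r];
    energy += k * dev * dev;
    double g = w * 2.0 * k * dev / d;
    grad(i, 0) += g * dx; grad(i, 1) += g * dy; grad(i, 2) += g * dz;
    grad(j, 0) -= g * dx; grad(j, 1) -= g * dy; grad(j, 2) -= g * dz;
  }
  return ndeg;
}

// Angle term shared by DAN (degrees) and stereochemical angles (radians).
// scale converts radians to the unit the deviation is expressed in.
static int angle_accumulate(const NumericMatrix& xyz, const IntegerVector& iv,
                            const IntegerVector& i1, const IntegerVector& i2,
                            const NumericVector& th_eq, double k, double w,
                            double scale, double& energy,
                            NumericMatrix& grad) {
  int ndeg = 0;
  for (int r = 0; r < iv.size(); ++r) {
    int v = iv[r], a = i1[r], b = i2[r];
    double ux = xyz(a, 0) - xyz(v, 0), uy = xyz(a, 1) - xyz(v, 1),
           uz = xyz(a, 2) - xyz(v, 2);
    double wx = xyz(b, 0) - xyz(v, 0), wy = xyz(b, 1) - xyz(v, 1),
           wz = xyz(b, 2) - xyz(v, 2);
    double nu2 = ux * ux + uy * uy + uz * uz;
    double nw2 = wx * wx + wy * wy + wz * wz;
    if (nu2 <= 1e-16 || nw2 <= 1e-16) { ++ndeg; continue; }
    double nu = std::sqrt(nu2), nw = std::sqrt(nw2);
    double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
    const double eps = 1e-9;
    if (c > 1.0 - eps) c = 1.0 - eps;
    if (c < -1.0 + eps) c = -1.0 + eps;
    double theta = std::acos(c) * scale;
    double s = std::sqrt(1.0 - c * c);
    double dev = theta - th_eq[r];
    energy += k * dev * dev;
    // dE/d(theta_rad) = 2 k dev * scale; dtheta_rad/dc = -1/sin
    double pref = -w * 2.0 * k * dev * scale / s;
    // dc/du = w/(nu nw) - c u/nu^2 ; dc/dw symmetric
    double gax = pref * (wx / (nu * nw) - c * ux / nu2);
    double gay = pref * (wy / (nu * nw) - c * uy / nu2);
    double gaz = pref * (wz / (nu * nw) - c * uz / nu2);
    double gbx = pref * (ux / (nu * nw) - c * wx / nw2);
    double gby = pref * (uy / (nu * nw) - c * wy / nw2);
    double gbz = pref * (uz / (nu * nw) - c * wz / nw2);
    grad(a, 0) += gax; grad(a, 1) += gay; grad(a, 2) += gaz;
    grad(b, 0) += gbx; grad(b, 1) += gby; grad(b, 2) += gbz;
    grad(v, 0) -= gax + gbx; grad(v, 1) -= gay + gby; grad(v, 2) -= gaz + gbz;
  }
  return ndeg;
}

// [[Rcpp::export]]
List cpp_den_energy_grad(NumericMatrix xyz, IntegerVector ia, IntegerVector ib,
                         NumericVector d_eq, double k) {
  double e = 0.0;
  NumericMatrix grad(xyz.nrow(), 3);
  int ndeg = den_accumulate(xyz, ia, ib, d_eq, k, 1.0, e, grad);
  return List::create(_["energy"] = e, _["gradient"] = grad,
                      _["n_degenerate"] = ndeg);
}

// [[Rcpp::export]]
List cpp_dan_energy_grad(NumericMatrix xyz, IntegerVector iv, IntegerVector i1,
                         IntegerVector i2, NumericVector theta_eq, double k) {
  double e = 0.0;
  NumericMatrix grad(xyz.nrow(), 3);
  int ndeg = angle_accumulate(xyz, iv, i1, i2, theta_eq, k, 1.0, R2D, e, grad);
  return List::create(_["energy"] = e, _["gradient"] = grad,
                      _["n_degenerate"] = ndeg);
}

// ---------------------------------------------------------------------------
// Simplified stereochemical energy: harmonic bonds + harmonic bond angles +
// quartic soft-sphere repulsion for nonbonded pairs inside the scaled
// radii sum.
// ---------------------------------------------------------------------------

static void stereo_accumulate(const NumericMatrix& xyz, const List& topo,
                              double vdw_scale, double w,
                              double& e_bond, double& e_angle, double& e_rep,
                              NumericMatrix& grad) {
  IntegerVector bi = topo["bond_i"], bj = topo["bond_j"];
  NumericVector bl = topo["bond_len"];
  double kb = as<double>(topo["k_bond"]);
  IntegerVector av = topo["angle_v"], a1 = topo["angle_i"], a2 = topo["angle_j"];
  NumericVector aid = topo["angle_rad"];
  double ka = as<double>(topo["k_angle"]);
  IntegerVector ni = topo["nb_i"], nj = topo["nb_j"];
  NumericVector nr = topo["nb_rsum"];
  double kr = as<double>(topo["k_rep"]);

  den_accumulate(xyz, bi, bj, bl, kb, w, e_bond, grad);
  angle_accumulate(xyz, av, a1, a2, aid, ka, w, 1.0, e_angle, grad);

  for (int r = 0; r < ni.size(); ++r) {
    int i = ni[r], j = nj[r];
    double rmin = nr[r] * vdw_scale;
    double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
           dz = xyz(i, 2) - xyz(j, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= rmin * rmin) continue;
    double d = std::sqrt(d2);
    if (d <= 1e-12) continue;
    double pen = rmin - d;
    double p2 = pen * pen;
    e_rep += kr * p2 * p2;
    double g = -w * 4.0 * kr * p2 * pen / d;
    grad(i, 0) += g * dx; grad(i, 1) += g * dy; grad(i, 2) += g * dz;
    grad(j, 0) -= g * dx; grad(j, 1) -= g * dy; grad(j, 2) -= g * dz;
  }
}

// [[Rcpp::export]]
List cpp_stereo_energy_grad(NumericMatrix xyz, List topo, double vdw_scale) {
  double eb = 0, ea = 0, er = 0;
  NumericMatrix grad(xyz.nrow(), 3);
  stereo_accumulate(xyz, topo, vdw_scale, 1.0, eb, ea, er, grad);
  return List::create(_["energy"] = eb + ea + er, _["e_bond"] = eb,
                      _["e_angle"] = ea, _["e_rep"] = er,
                      _["gradient"] = grad);
}

// ---------------------------------------------------------------------------
// Structure factors (direct summation, orthogonal P1 cell) and the
// least-squares amplitude target with closed-form scale.
// ---------------------------------------------------------------------------

// Per-atom phase tables exp(2*pi*i*h*x/a), indexed h = -hmax..hmax with an
// offset so the inner loop is branch-free; three complex multiplies give
// the phase of any reflection.
struct PhaseWorkspace {
  std::vector<int> h, k, l;         // Miller indices, offset by hmax
  int hx, hy, hz;
  std::vector<double> pxr, pxi, pyr, pyi, pzr, pzi;

  void init(const IntegerMatrix& hkl) {
    int m = hkl.nrow();
    h.resize(m); k.resize(m); l.resize(m);
    hx = hy = hz = 0;
    for (int r = 0; r < m; ++r) {
      hx = std::max(hx, std::abs(hkl(r, 0)));
      hy = std::max(hy, std::abs(hkl(r, 1)));
      hz = std::max(hz, std::abs(hkl(r, 2)));
    }
    for (int r = 0; r < m; ++r) {
      h[r] = hkl(r, 0) + hx; k[r] = hkl(r, 1) + hy; l[r] = hkl(r, 2) + hz;
    }
    pxr.resize(2 * hx + 1); pxi.resize(2 * hx + 1);
    pyr.resize(2 * hy + 1); pyi.resize(2 * hy + 1);
    pzr.resize(2 * hz + 1); pzi.resize(2 * hz + 1);
  }

  static void fill(double* pr, double* pi, int hmax, double phase) {
    pr[hmax] = 1.0; pi[hmax] = 0.0;
    double cr = std::cos(phase), ci = std::sin(phase);
    for (int t = 1; t <= hmax; ++t) {
      pr[hmax + t] = pr[hmax + t - 1] * cr - pi[hmax + t - 1] * ci;
      pi[hmax + t] = pr[hmax + t - 1] * ci + pi[hmax + t - 1] * cr;
      pr[hmax - t] = pr[hmax + t];
      pi[hmax - t] = -pi[hmax + t];
    }
  }

  void set_atom(const NumericMatrix& xyz, const NumericVector& cell, int a) {
    fill(&pxr[0], &pxi[0], hx, TWOPI * xyz(a, 0) / cell[0]);
    fill(&pyr[0], &pyi[0], hy, TWOPI * xyz(a, 1) / cell[1]);
    fill(&pzr[0], &pzi[0], hz, TWOPI * xyz(a, 2) / cell[2]);
  }

  // phase factor exp(2*pi*i*h.x_frac) of reflection r for the current atom
  inline void phase(int r, double& re, double& im) const {
    double ar = pxr[h[r]], ai = pxi[h[r]];
    double br = pyr[k[r]], bi = pyi[k[r]];
    double t1 = ar * br - ai * bi, t2 = ar * bi + ai * br;
    re = t1 * pzr[l[r]] - t2 * pzi[l[r]];
    im = t1 * pzi[l[r]] + t2 * pzr[l[r]];
  }
};

// [[Rcpp::export]]
ComplexVector cpp_structure_factors(NumericMatrix xyz, NumericVector cell,
                                    IntegerMatrix hkl, NumericVector z,
                                    double b_overall) {
  int n = xyz.nrow(), m = hkl.nrow();
  std::vector<double> Fr(m, 0.0), Fi(m, 0.0);
  PhaseWorkspace ws;
  ws.init(hkl);
  for (int a = 0; a < n; ++a) {
    ws.set_atom(xyz, cell, a);
    double za = z[a];
    for (int r = 0; r < m; ++r) {
      double re, im;
      ws.phase(r, re, im);
      Fr[r] += za * re; Fi[r] += za * im;
    }
  }
  ComplexVector out(m);
  for (int r = 0; r < m; ++r) {
    double s2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      double q = hkl(r, c) / cell[c];
      s2 += q * q;
    }
    double damp = std::exp(-b_overall * s2 / 4.0);
    out[r] = Rcomplex{Fr[r] * damp, Fi[r] * damp};
  }
  return out;
}

// Least-squares amplitude target over the working set:
//   E = sum_work (fobs - s*|Fcalc|)^2,  s = argmin (closed form).
// The gradient treats s as constant, exact at the optimal scale.
// Free reflections contribute nothing.
static double exp_accumulate(const NumericMatrix& xyz,
                             const NumericVector& cell,
                             const IntegerMatrix& hkl, const NumericVector& z,
                             double b_overall, const NumericVector& fobs,
                             const LogicalVector& work, double w,
                             bool want_grad, NumericMatrix& grad,
                             double& scale_out, PhaseWorkspace& ws) {
  int n = xyz.nrow(), m = hkl.nrow();
  std::vector<double> Fr(m, 0.0), Fi(m, 0.0), damp(m), qx(m), qy(m), qz(m);
  for (int r = 0; r < m; ++r) {
    qx[r] = hkl(r, 0) / cell[0]; qy[r] = hkl(r, 1) / cell[1];
    qz[r] = hkl(r, 2) / cell[2];
    double s2 = qx[r] * qx[r] + qy[r] * qy[r] + qz[r] * qz[r];
    damp[r] = std::exp(-b_overall * s2 / 4.0);
  }
  // pass 1: undamped structure-factor sums U = sum_a z_a exp(2 pi i h.x)
  for (int a = 0; a < n; ++a) {
    ws.set_atom(xyz, cell, a);
    double za = z[a];
    for (int r = 0; r < m; ++r) {
      double re, im;
      ws.phase(r, re, im);
      Fr[r] += za * re; Fi[r] += za * im;
    }
  }
  double num = 0.0, den = 0.0;
  std::vector<double> absF(m);
  for (int r = 0; r < m; ++r) {
    absF[r] = damp[r] * std::sqrt(Fr[r] * Fr[r] + Fi[r] * Fi[r]);
    if (work[r]) { num += fobs[r] * absF[r]; den += absF[r] * absF[r]; }
  }
  double s = den > 0 ? num / den : 0.0;
  scale_out = s;
  double energy = 0.0;
  // gradient prefactors per reflection (zero for free / ill-defined ones):
  //   dE/d|F| = -2 s dev,  d|F|/dx_{a,k} = -(damp^2/|F|) 2 pi q_k Im(conj(U) term)
  std::vector<double> Qx(m), Qy(m), Qz(m);
  for (int r = 0; r < m; ++r) {
    double q = 0.0;
    if (work[r]) {
      double dev = fobs[r] - s * absF[r];
      energy += dev * dev;
      if (want_grad && absF[r] > 1e-12)
        q = w * (-2.0 * s * dev) * (-TWOPI) * damp[r] * damp[r] / absF[r];
    }
    Qx[r] = q * qx[r]; Qy[r] = q * qy[r]; Qz[r] = q * qz[r];
  }
  if (want_grad) {
    // pass 2: recompute each atom's phases and project onto the prefactors
    for (int a = 0; a < n; ++a) {
      ws.set_atom(xyz, cell, a);
      double za = z[a];
      double gx = 0, gy = 0, gz = 0;
      for (int r = 0; r < m; ++r) {
        double re, im;
        ws.phase(r, re, im);
        double cross = za * (Fr[r] * im - Fi[r] * re);
        gx += Qx[r] * cross; gy += Qy[r] * cross; gz += Qz[r] * cross;
      }
      grad(a, 0) += gx; grad(a, 1) += gy; grad(a, 2) += gz;
    }
  }
  return energy;
}

// [[Rcpp::export]]
List cpp_exp_energy_grad(NumericMatrix xyz, NumericVector cell,
                         IntegerMatrix hkl, NumericVector z, double b_overall,
                         NumericVector fobs, LogicalVector work,
                         bool want_grad) {
  NumericMatrix grad(xyz.nrow(), 3);
  double s = 0.0;
  PhaseWorkspace ws;
  ws.init(hkl);
  double e = exp_accumulate(xyz, cell, hkl, z, b_overall, fobs, work, 1.0,
                            want_grad, grad, s, ws);
  return List::create(_["energy"] = e, _["gradient"] = grad, _["scale"] = s);
}

// ---------------------------------------------------------------------------
// Velocity-Verlet segment (unit masses).  Forces = -gradient of
//   E_stereo + w_a * E_exp + w_dcn * (E_den + E_dan),
// componentwise capped at force_cap as a numerical guard during hot
// annealing.  Returns updated coordinates/velocities and the final energy
// decomposition; ok=false if anything went non-finite.
// ---------------------------------------------------------------------------

struct ForceResult {
  double e_bond, e_angle, e_rep, e_exp, e_den, e_dan, scale;
  bool ok;
};

static ForceResult total_force(const NumericMatrix& xyz, const List& topo,
                               double vdw_scale, const List& xray,
                               double w_a, const List& dcn, double w_dcn,
                               double k_pair, double k_angle,
                               double force_cap, NumericMatrix& grad,
                               PhaseWorkspace& ws) {
  ForceResult res = {0, 0, 0, 0, 0, 0, 0, true};
  std::fill(grad.begin(), grad.end(), 0.0);
  stereo_accumulate(xyz, topo, vdw_scale, 1.0,
                    res.e_bond, res.e_angle, res.e_rep, grad);
  if (w_a > 0) {
    NumericVector cell = xray["cell"];
    IntegerMatrix hkl = xray["hkl"];
    NumericVector z = xray["z"], fobs = xray["fobs"];
    LogicalVector work = xray["work"];
    double b_overall = as<double>(xray["b_overall"]);
    res.e_exp = exp_accumulate(xyz, cell, hkl, z, b_overall, fobs, work,
                               w_a, true, grad, res.scale, ws);
  }
  if (w_dcn > 0) {
    IntegerVector pa = dcn["pair_a"], pb = dcn["pair_b"];
    NumericVector deq = dcn["d_eq"];
    IntegerVector av = dcn["ang_v"], a1 = dcn["ang_t1"], a2 = dcn["ang_t2"];
    NumericVector teq = dcn["theta_eq"];
    den_accumulate(xyz, pa, pb, deq, k_pair, w_dcn, res.e_den, grad);
    angle_accumulate(xyz, av, a1, a2, teq, k_angle, w_dcn, R2D, res.e_dan,
                     grad);
  }
  for (int i = 0; i < grad.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      double g = grad(i, k);
      if (!std::isfinite(g)) { res.ok = false; return res; }
      if (g > force_cap) grad(i, k) = force_cap;
      else if (g < -force_cap) grad(i, k) = -force_cap;
    }
  return res;
}

// [[Rcpp::export]]
List cpp_md_segment(NumericMatrix xyz_in, NumericMatrix vel_in, int nsteps,
                    double dt, List topo, double vdw_scale, List xray,
                    double w_a, List dcn, double w_dcn, double k_pair,
                    double k_angle, double force_cap) {
  NumericMatrix xyz = clone(xyz_in), vel = clone(vel_in);
  int n = xyz.nrow();
  NumericMatrix grad(n, 3);
  PhaseWorkspace ws;
  if (w_a > 0) {
    IntegerMatrix hkl = xray["hkl"];
    ws.init(hkl);
  }
  ForceResult fr = total_force(xyz, topo, vdw_scale, xray, w_a, dcn, w_dcn,
                               k_pair, k_angle, force_cap, grad, ws);
  bool ok = fr.ok;
  for (int step = 0; step < nsteps && ok; ++step) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        vel(i, k) -= 0.5 * dt * grad(i, k);
        xyz(i, k) += dt * vel(i, k);
        if (!std::isfinite(xyz(i, k))) ok = false;
      }
    if (!ok) break;
    fr = total_force(xyz, topo, vdw_scale, xray, w_a, dcn, w_dcn,
                     k_pair, k_angle, force_cap, grad, ws);
    ok = fr.ok;
    if (!ok) break;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        vel(i, k) -= 0.5 * dt * grad(i, k);
  }
  double e_stereo = fr.e_bond + fr.e_angle + fr.e_rep;
  return List::create(_["xyz"] = xyz, _["vel"] = vel, _["ok"] = ok,
                      _["e_stereo"] = e_stereo, _["e_exp"] = fr.e_exp,
                      _["e_den"] = fr.e_den, _["e_dan"] = fr.e_dan,
                      _["scale"] = fr.scale);
}
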