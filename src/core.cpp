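// Core MD engine for the rWAIL water potential.
//
// Internal units: Angstrom, ps, kcal/mol, amu, e, K.  The R layer converts
// from the user-facing nm/GRO conventions at this boundary.
//
// Layout conventions: physical sites only (O, H1, H2 per molecule, in that
// order); the massless M site is reconstructed on every evaluation and its
// force redistributed onto the physical sites with the constant weights
// (1-2a, a, a) that follow from the linear virtual-site rule.

#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double KE    = 332.06371;      // kcal A / (mol e^2)
static const double KB    = 1.987204259e-3; // kcal / (mol K)
static const double FCONV = 418.4;          // kcal/mol/A -> amu A / ps^2
static const double MASS_O = 15.999, MASS_H = 1.008;

struct FF {
  double qM, qH, a, AOO, alpha, COO, A4, rc, re, thetaE, k2, k3, k4, kTheta;
  bool flexible;
};

static FF parseFF(const List& ff) {
  FF p;
  p.qM = ff["qM"]; p.qH = ff["qH"]; p.a = ff["a"];
  p.AOO = ff["AOO"]; p.alpha = ff["alpha"]; p.COO = ff["COO"];
  p.A4 = ff["A4"]; p.rc = ff["rc"]; p.re = ff["re"];
  p.thetaE = ff["thetaE"];   // radians (converted in R)
  p.flexible = as<bool>(ff["flexible"]);
  if (p.flexible) {
    p.k2 = ff["k2"]; p.k3 = ff["k3"]; p.k4 = ff["k4"]; p.kTheta = ff["kTheta"];
  } else {
    p.k2 = p.k3 = p.k4 = p.kTheta = 0.0;
  }
  return p;
}

struct EnergyAcc {
  double coulomb = 0, repulsion = 0, dispersion = 0, hb = 0, intra = 0,
         lrc = 0;
  double vir[9] = {0,0,0,0,0,0,0,0,0};   // atomic virial sum r_ij (x) F_ij
  double total() const {
    return coulomb + repulsion + dispersion + hb + intra + lrc;
  }
};

static inline void addVir(double* vir, const double* rij, const double* fij) {
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      vir[3 * a + b] += rij[a] * fij[b];
}

// ---------------------------------------------------------------------------
// Reciprocal-space Ewald over an arbitrary charged-site list.
// Adds energy to *energy, forces (kcal/mol/A) into f (3*n), and the
// reciprocal virial tensor into vir.
static void ewaldRecip(const std::vector<double>& r,
                       const std::vector<double>& q,
                       const double* box, double alpha,
                       const int* kmax, double kcut2,
                       std::vector<double>& f, double* vir, double* energy) {
  const int n = (int)q.size();
  const double V = box[0] * box[1] * box[2];
  const double twoPi = 2.0 * M_PI;
  // per-axis complex exponentials e^{i 2 pi m x / L}, m = 0..kmax[axis]
  std::vector<std::complex<double>> ex((kmax[0] + 1) * n),
      ey((kmax[1] + 1) * n), ez((kmax[2] + 1) * n);
  for (int i = 0; i < n; ++i) {
    ex[i] = ey[i] = ez[i] = std::complex<double>(1.0, 0.0);
    std::complex<double> px(std::cos(twoPi * r[3 * i] / box[0]),
                            std::sin(twoPi * r[3 * i] / box[0]));
    std::complex<double> py(std::cos(twoPi * r[3 * i + 1] / box[1]),
                            std::sin(twoPi * r[3 * i + 1] / box[1]));
    std::complex<double> pz(std::cos(twoPi * r[3 * i + 2] / box[2]),
                            std::sin(twoPi * r[3 * i + 2] / box[2]));
    for (int m = 1; m <= kmax[0]; ++m) ex[m * n + i] = ex[(m - 1) * n + i] * px;
    for (int m = 1; m <= kmax[1]; ++m) ey[m * n + i] = ey[(m - 1) * n + i] * py;
    for (int m = 1; m <= kmax[2]; ++m) ez[m * n + i] = ez[(m - 1) * n + i] * pz;
  }
  std::vector<double> exyRe(n), exyIm(n), eikRe(n), eikIm(n);
  for (int mx = 0; mx <= kmax[0]; ++mx) {
    double kx = twoPi * mx / box[0];
    for (int my = (mx == 0 ? 0 : -kmax[1]); my <= kmax[1]; ++my) {
      double ky = twoPi * my / box[1];
      if (kx * kx + ky * ky > kcut2) continue;
      const std::complex<double>* exp_ = &ex[mx * n];
      const std::complex<double>* eyp = &ey[std::abs(my) * n];
      const double ysgn = (my >= 0) ? 1.0 : -1.0;
      for (int i = 0; i < n; ++i) {
        double ar = exp_[i].real(), ai = exp_[i].imag();
        double br = eyp[i].real(), bi = ysgn * eyp[i].imag();
        exyRe[i] = ar * br - ai * bi;
        exyIm[i] = ar * bi + ai * br;
      }
      for (int mz = ((mx == 0 && my == 0) ? 1 : -kmax[2]); mz <= kmax[2]; ++mz) {
        double kz = twoPi * mz / box[2];
        double k2 = kx * kx + ky * ky + kz * kz;
        if (k2 > kcut2) continue;
        const std::complex<double>* ezp = &ez[std::abs(mz) * n];
        const double zsgn = (mz >= 0) ? 1.0 : -1.0;
        double sRe = 0.0, sIm = 0.0;
        for (int i = 0; i < n; ++i) {
          double zr = ezp[i].real(), zi = zsgn * ezp[i].imag();
          double rr = exyRe[i] * zr - exyIm[i] * zi;
          double ri = exyRe[i] * zi + exyIm[i] * zr;
          eikRe[i] = rr; eikIm[i] = ri;
          sRe += q[i] * rr; sIm += q[i] * ri;
        }
        double Ak = std::exp(-k2 / (4.0 * alpha * alpha)) / k2;
        double Ek = 2.0 * KE * (twoPi / V) * Ak * (sRe * sRe + sIm * sIm);
        *energy += Ek;
        double fpref = 2.0 * KE * (4.0 * M_PI / V) * Ak;
        for (int i = 0; i < n; ++i) {
          // F_i = pref * q_i * k * Im(conj(S) e^{ik.r_i})
          double im = sRe * eikIm[i] - sIm * eikRe[i];
          double c = fpref * q[i] * im;
          f[3 * i]     += c * kx;
          f[3 * i + 1] += c * ky;
          f[3 * i + 2] += c * kz;
        }
        double fac = 2.0 * (1.0 / k2 + 1.0 / (4.0 * alpha * alpha));
        double kv[3] = {kx, ky, kz};
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            vir[3 * a + b] += Ek * ((a == b ? 1.0 : 0.0) - fac * kv[a] * kv[b]);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Full energy/forces for a periodic water system.
//
// pos: 3*nphys doubles (O,H1,H2 per molecule); f resized/filled with the
// redistributed forces on physical sites.  Returns the energy breakdown and
// the MOLECULAR virial (pair/atomic virial corrected by -sum dr_i (x) F_i).
static void waterForces(const std::vector<double>& pos, const double* box,
                        const FF& ff, double ewAlpha, const int* ewKmax,
                        double ewKcut2,
                        double rcut, bool lrcE, bool lrcP, bool interact,
                        std::vector<double>& f, EnergyAcc& E,
                        double* virMol) {
  const int nphys = (int)pos.size() / 3;
  const int nmol = nphys / 3;
  f.assign(3 * nphys, 0.0);
  std::memset(virMol, 0, 9 * sizeof(double));
  if (!interact) return;

  const double V = box[0] * box[1] * box[2];
  // M positions and M-force accumulator
  std::vector<double> rm(3 * nmol), fm(3 * nmol, 0.0);
  const double wO = 1.0 - 2.0 * ff.a, wH = ff.a;
  for (int m = 0; m < nmol; ++m) {
    const double* O = &pos[9 * m];
    const double* H1 = &pos[9 * m + 3];
    const double* H2 = &pos[9 * m + 6];
    for (int d = 0; d < 3; ++d)
      rm[3 * m + d] = O[d] + ff.a * ((H1[d] - O[d]) + (H2[d] - O[d]));
  }

  const double rc2 = rcut * rcut;
  const double qs[3] = {ff.qH, ff.qH, ff.qM};
  const double sqrtPi = std::sqrt(M_PI);

  // --- real space: molecule-based cutoff on the O-O minimum image ---------
  for (int mi = 0; mi < nmol - 1; ++mi) {
    const double* Oi = &pos[9 * mi];
    for (int mj = mi + 1; mj < nmol; ++mj) {
      const double* Oj = &pos[9 * mj];
      // sh is added to every site of molecule j to get its nearest image
      double sh[3], dOO[3];
      for (int d = 0; d < 3; ++d) {
        double dd = Oi[d] - Oj[d];
        sh[d] = box[d] * std::nearbyint(dd / box[d]);
        dOO[d] = dd - sh[d];
      }
      double r2 = dOO[0] * dOO[0] + dOO[1] * dOO[1] + dOO[2] * dOO[2];
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r < 0.5)
        stop("unphysical O-O overlap at %.3g A between molecules %d and %d",
             r, mi + 1, mj + 1);
      // O-O Born-Mayer + dispersion
      {
        double eRep = ff.AOO * std::exp(-ff.alpha * r);
        double eDisp = -ff.COO / (r2 * r2 * r2);
        E.repulsion += eRep;
        E.dispersion += eDisp;
        double dudr = -ff.alpha * eRep + 6.0 * ff.COO / (r2 * r2 * r2 * r);
        double c = -dudr / r;
        double fij[3];
        for (int d = 0; d < 3; ++d) {
          fij[d] = c * dOO[d];
          f[9 * mi + d] += fij[d];
          f[9 * mj + d] -= fij[d];
        }
        addVir(E.vir, dOO, fij);
      }
      // charged-site pairs (H1,H2,M) x (H1,H2,M): erfc Coulomb
      const double* ci[3] = {&pos[9 * mi + 3], &pos[9 * mi + 6], &rm[3 * mi]};
      const double* cj[3] = {&pos[9 * mj + 3], &pos[9 * mj + 6], &rm[3 * mj]};
      double* fi[3] = {&f[9 * mi + 3], &f[9 * mi + 6], &fm[3 * mi]};
      double* fj[3] = {&f[9 * mj + 3], &f[9 * mj + 6], &fm[3 * mj]};
      for (int a = 0; a < 3; ++a) {
        for (int b = 0; b < 3; ++b) {
          double rij[3];
          for (int d = 0; d < 3; ++d) rij[d] = ci[a][d] - (cj[b][d] + sh[d]);
          double s2 = rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2];
          double s = std::sqrt(s2);
          if (s < 1e-8) stop("coincident charge sites across molecules");
          double qq = KE * qs[a] * qs[b];
          double erfcv = std::erfc(ewAlpha * s);
          E.coulomb += qq * erfcv / s;
          double dudr = -qq * (erfcv / s2 +
                        2.0 * ewAlpha / sqrtPi * std::exp(-ewAlpha * ewAlpha * s2) / s);
          double c = -dudr / s;
          double fij[3];
          for (int d = 0; d < 3; ++d) {
            fij[d] = c * rij[d];
            fi[a][d] += fij[d];
            fj[b][d] -= fij[d];
          }
          addVir(E.vir, rij, fij);
        }
      }
      // hydrogen-bond wall: M_i - H_j and M_j - H_i
      for (int swap = 0; swap < 2; ++swap) {
        const double* M = swap ? cj[2] : ci[2];
        double* FM = swap ? fj[2] : fi[2];
        for (int hb = 0; hb < 2; ++hb) {
          const double* H = swap ? ci[hb] : cj[hb];
          double* FH = swap ? fi[hb] : fj[hb];
          double rij[3];
          for (int d = 0; d < 3; ++d) {
            double hh = swap ? (H[d]) : (H[d] + sh[d]);
            double mm = swap ? (M[d] + sh[d]) : M[d];
            rij[d] = mm - hh;
          }
          double s = std::sqrt(rij[0] * rij[0] + rij[1] * rij[1] +
                               rij[2] * rij[2]);
          if (s >= ff.rc) continue;
          double dr = s - ff.rc;
          E.hb += ff.A4 * dr * dr * dr * dr;
          double dudr = 4.0 * ff.A4 * dr * dr * dr;
          double c = -dudr / s;
          double fij[3];
          for (int d = 0; d < 3; ++d) {
            fij[d] = c * rij[d];
            FM[d] += fij[d];
            FH[d] -= fij[d];
          }
          addVir(E.vir, rij, fij);
        }
      }
    }
  }

  // --- reciprocal space over charged sites --------------------------------
  {
    const int nq = 3 * nmol;
    std::vector<double> rq(3 * nq), qq(nq), fq(3 * nq, 0.0);
    for (int m = 0; m < nmol; ++m) {
      for (int d = 0; d < 3; ++d) {
        rq[3 * (3 * m) + d]     = pos[9 * m + 3 + d];  // H1
        rq[3 * (3 * m + 1) + d] = pos[9 * m + 6 + d];  // H2
        rq[3 * (3 * m + 2) + d] = rm[3 * m + d];       // M
      }
      qq[3 * m] = ff.qH; qq[3 * m + 1] = ff.qH; qq[3 * m + 2] = ff.qM;
    }
    double erec = 0.0;
    ewaldRecip(rq, qq, box, ewAlpha, ewKmax, ewKcut2, fq, E.vir, &erec);
    E.coulomb += erec;
    for (int m = 0; m < nmol; ++m)
      for (int d = 0; d < 3; ++d) {
        f[9 * m + 3 + d] += fq[3 * (3 * m) + d];
        f[9 * m + 6 + d] += fq[3 * (3 * m + 1) + d];
        fm[3 * m + d]    += fq[3 * (3 * m + 2) + d];
      }
  }

  // --- self energy and intramolecular exclusion corrections ---------------
  {
    double q2sum = nmol * (2.0 * ff.qH * ff.qH + ff.qM * ff.qM);
    E.coulomb -= KE * ewAlpha / sqrtPi * q2sum;
    for (int m = 0; m < nmol; ++m) {
      const double* s1[3] = {&pos[9 * m + 3], &pos[9 * m + 6], &rm[3 * m]};
      double* f1[3] = {&f[9 * m + 3], &f[9 * m + 6], &fm[3 * m]};
      const double qv[3] = {ff.qH, ff.qH, ff.qM};
      for (int a = 0; a < 3; ++a) {
        for (int b = a + 1; b < 3; ++b) {
          double rij[3];
          for (int d = 0; d < 3; ++d) rij[d] = s1[a][d] - s1[b][d];
          double s2 = rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2];
          double s = std::sqrt(s2);
          double qqp = KE * qv[a] * qv[b];
          double erfv = std::erf(ewAlpha * s);
          E.coulomb -= qqp * erfv / s;
          // U_excl = -qq erf(ar)/r
          double dudr = -qqp * (2.0 * ewAlpha / sqrtPi *
                        std::exp(-ewAlpha * ewAlpha * s2) / s - erfv / s2);
          double c = -dudr / s;
          double fij[3];
          for (int d = 0; d < 3; ++d) {
            fij[d] = c * rij[d];
            f1[a][d] += fij[d];
            f1[b][d] -= fij[d];
          }
          addVir(E.vir, rij, fij);
        }
      }
    }
  }

  // --- intramolecular potential (flexible variant) ------------------------
  if (ff.flexible) {
    for (int m = 0; m < nmol; ++m) {
      double* O = (double*)&pos[9 * m];
      double* H[2] = {(double*)&pos[9 * m + 3], (double*)&pos[9 * m + 6]};
      double* fO = &f[9 * m];
      double* fH[2] = {&f[9 * m + 3], &f[9 * m + 6]};
      double u[2][3], lu[2];
      for (int h = 0; h < 2; ++h) {
        for (int d = 0; d < 3; ++d) u[h][d] = H[h][d] - O[d];
        lu[h] = std::sqrt(u[h][0] * u[h][0] + u[h][1] * u[h][1] +
                          u[h][2] * u[h][2]);
        double dr = lu[h] - ff.re;
        E.intra += 0.5 * ff.k2 * dr * dr + ff.k3 * dr * dr * dr / 3.0 +
                   0.25 * ff.k4 * dr * dr * dr * dr;
        double dudr = ff.k2 * dr + ff.k3 * dr * dr + ff.k4 * dr * dr * dr;
        double c = -dudr / lu[h];
        double fij[3];
        for (int d = 0; d < 3; ++d) {
          fij[d] = c * u[h][d];
          fH[h][d] += fij[d];
          fO[d] -= fij[d];
        }
        addVir(E.vir, u[h], fij);
      }
      double cosT = (u[0][0] * u[1][0] + u[0][1] * u[1][1] +
                     u[0][2] * u[1][2]) / (lu[0] * lu[1]);
      cosT = std::max(-1.0, std::min(1.0, cosT));
      double theta = std::acos(cosT);
      double dth = theta - ff.thetaE;
      E.intra += 0.5 * ff.kTheta * dth * dth;
      double dudth = ff.kTheta * dth;
      double sinT = std::sqrt(std::max(1e-12, 1.0 - cosT * cosT));
      // dtheta/du1 = -(u2hat - cos*u1hat)/(|u1| sin); F_H1 = -dU/du1
      double fH1[3], fH2[3];
      for (int d = 0; d < 3; ++d) {
        fH1[d] = dudth / (lu[0] * sinT) *
                 (u[1][d] / lu[1] - cosT * u[0][d] / lu[0]);
        fH2[d] = dudth / (lu[1] * sinT) *
                 (u[0][d] / lu[0] - cosT * u[1][d] / lu[1]);
      }
      for (int d = 0; d < 3; ++d) {
        fH[0][d] += fH1[d];
        fH[1][d] += fH2[d];
        fO[d] -= (fH1[d] + fH2[d]);
      }
      addVir(E.vir, u[0], fH1);
      addVir(E.vir, u[1], fH2);
    }
  }

  // --- long-range dispersion corrections ----------------------------------
  double plrc = 0.0;
  if (lrcE)
    E.lrc = -2.0 * M_PI * nmol * nmol * ff.COO / (3.0 * V * rcut * rcut * rcut);
  if (lrcP) {
    double rho = nmol / V;
    plrc = -4.0 * M_PI * rho * rho * ff.COO / (3.0 * rcut * rcut * rcut);
    for (int a = 0; a < 3; ++a) E.vir[3 * a + a] += plrc * V;
  }

  // --- M-site force redistribution ----------------------------------------
  for (int m = 0; m < nmol; ++m)
    for (int d = 0; d < 3; ++d) {
      f[9 * m + d]     += wO * fm[3 * m + d];
      f[9 * m + 3 + d] += wH * fm[3 * m + d];
      f[9 * m + 6 + d] += wH * fm[3 * m + d];
    }

  // --- molecular virial: atomic minus sum (r_i - R_com) (x) F_i -----------
  double corr[9] = {0,0,0,0,0,0,0,0,0};
  for (int m = 0; m < nmol; ++m) {
    double com[3] = {0, 0, 0};
    const double mm[3] = {MASS_O, MASS_H, MASS_H};
    double Mtot = MASS_O + 2 * MASS_H;
    for (int s = 0; s < 3; ++s)
      for (int d = 0; d < 3; ++d)
        com[d] += mm[s] * pos[9 * m + 3 * s + d] / Mtot;
    for (int s = 0; s < 3; ++s)
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          corr[3 * a + b] += (pos[9 * m + 3 * s + a] - com[a]) *
                             f[9 * m + 3 * s + b];
  }
  for (int k = 0; k < 9; ++k) virMol[k] = E.vir[k] - corr[k];
}

// ---------------------------------------------------------------------------
// Rigid constraints: SHAKE/RATTLE on the three intramolecular distances.

struct Constraints {
  double dOH2, dHH2;   // squared targets
  int maxIter = 1000;
  double tol = 1e-12;  // relative tolerance on squared distances
};

static void shakeStep(std::vector<double>& r, std::vector<double>& v,
                      const std::vector<double>& r0, double dt,
                      const Constraints& con, int nmol) {
  const double mass[3] = {MASS_O, MASS_H, MASS_H};
  const int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  const double d2[3] = {con.dOH2, con.dOH2, con.dHH2};
  for (int m = 0; m < nmol; ++m) {
    bool done = false;
    for (int it = 0; it < con.maxIter && !done; ++it) {
      done = true;
      for (int c = 0; c < 3; ++c) {
        int i = 9 * m + 3 * pairs[c][0], j = 9 * m + 3 * pairs[c][1];
        double s[3], s0[3];
        double ss = 0, ss0 = 0;
        for (int d = 0; d < 3; ++d) {
          s[d] = r[i + d] - r[j + d];
          s0[d] = r0[i + d] - r0[j + d];
          ss += s[d] * s[d];
          ss0 += s[d] * s0[d];
        }
        double diff = ss - d2[c];
        if (std::fabs(diff) > con.tol * d2[c]) {
          done = false;
          double mi = mass[pairs[c][0]], mj = mass[pairs[c][1]];
          double g = diff / (2.0 * ss0 * (1.0 / mi + 1.0 / mj));
          for (int d = 0; d < 3; ++d) {
            double dx = g * s0[d];
            r[i + d] -= dx / mi;
            r[j + d] += dx / mj;
            v[i + d] -= dx / (mi * dt);
            v[j + d] += dx / (mj * dt);
          }
        }
      }
    }
    if (!done)
      stop("SHAKE did not converge for molecule %d", m + 1);
  }
}

static void rattleVelocities(const std::vector<double>& r,
                             std::vector<double>& v, const Constraints& con,
                             int nmol) {
  const double mass[3] = {MASS_O, MASS_H, MASS_H};
  const int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  for (int m = 0; m < nmol; ++m) {
    bool done = false;
    for (int it = 0; it < con.maxIter && !done; ++it) {
      done = true;
      for (int c = 0; c < 3; ++c) {
        int i = 9 * m + 3 * pairs[c][0], j = 9 * m + 3 * pairs[c][1];
        double s[3], sv = 0, ss = 0;
        for (int d = 0; d < 3; ++d) {
          s[d] = r[i + d] - r[j + d];
          sv += s[d] * (v[i + d] - v[j + d]);
          ss += s[d] * s[d];
        }
        double mi = mass[pairs[c][0]], mj = mass[pairs[c][1]];
        if (std::fabs(sv) > 1e-10) {
          done = false;
          double k = sv / (ss * (1.0 / mi + 1.0 / mj));
          for (int d = 0; d < 3; ++d) {
            v[i + d] -= k * s[d] / mi;
            v[j + d] += k * s[d] / mj;
          }
        }
      }
    }
    if (!done) stop("RATTLE velocity stage did not converge");
  }
}

// ---------------------------------------------------------------------------
// Exported single-point evaluators.

// [[Rcpp::export]]
List cppEnergyForces(NumericMatrix posA, NumericVector boxA, List ff,
                     double ewAlpha, IntegerVector ewKmax, double ewKcut2,
                     double rcut,
                     bool lrcE, bool lrcP, bool interact = true) {
  int nphys = posA.nrow();
  if (nphys % 3 != 0) stop("positions must hold 3 physical sites/molecule");
  double box[3] = {boxA[0], boxA[1], boxA[2]};
  for (int d = 0; d < 3; ++d)
    if (box[d] < 2.0 * rcut)
      stop("box length %.3g A is shorter than twice the cutoff %.3g A",
           box[d], rcut);
  std::vector<double> pos(3 * nphys);
  for (int i = 0; i < nphys; ++i)
    for (int d = 0; d < 3; ++d) pos[3 * i + d] = posA(i, d);
  FF p = parseFF(ff);
  int km[3] = {ewKmax[0], ewKmax[1], ewKmax[2]};
  std::vector<double> f;
  EnergyAcc E;
  double virMol[9];
  waterForces(pos, box, p, ewAlpha, km, ewKcut2, rcut, lrcE, lrcP, interact,
              f, E, virMol);
  NumericMatrix fo(nphys, 3), vm(3, 3), va(3, 3);
  for (int i = 0; i < nphys; ++i)
    for (int d = 0; d < 3; ++d) fo(i, d) = f[3 * i + d];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      vm(a, b) = virMol[3 * a + b];
      va(a, b) = E.vir[3 * a + b];
    }
  return List::create(_["coulomb"] = E.coulomb, _["repulsion"] = E.repulsion,
                      _["dispersion"] = E.dispersion, _["hb"] = E.hb,
                      _["intra"] = E.intra, _["lrc"] = E.lrc,
                      _["total"] = E.total(), _["forces"] = fo,
                      _["virialMolecular"] = vm, _["virialAtomic"] = va);
}

// Generic point-charge Ewald (reference path; used for lattice checks).
// [[Rcpp::export]]
List cppEwald(NumericMatrix posA, NumericVector q, NumericVector boxA,
              double ewAlpha, IntegerVector ewKmax, double ewKcut2,
              double rcut) {
  int n = posA.nrow();
  double box[3] = {boxA[0], boxA[1], boxA[2]};
  for (int d = 0; d < 3; ++d)
    if (box[d] < 2.0 * rcut)
      stop("box length %.3g A is shorter than twice the cutoff %.3g A",
           box[d], rcut);
  double qtot = 0;
  for (int i = 0; i < n; ++i) qtot += q[i];
  if (std::fabs(qtot) > 1e-9)
    stop("Ewald summation requires a neutral system (net charge %.3g e)", qtot);
  std::vector<double> r(3 * n), f(3 * n, 0.0), qv(n);
  for (int i = 0; i < n; ++i) {
    qv[i] = q[i];
    for (int d = 0; d < 3; ++d) r[3 * i + d] = posA(i, d);
  }
  double vir[9] = {0,0,0,0,0,0,0,0,0};
  double energy = 0.0;
  const double sqrtPi = std::sqrt(M_PI);
  const double rc2 = rcut * rcut;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double rij[3];
      for (int d = 0; d < 3; ++d) {
        double dd = r[3 * i + d] - r[3 * j + d];
        dd -= box[d] * std::nearbyint(dd / box[d]);
        rij[d] = dd;
      }
      double s2 = rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2];
      if (s2 >= rc2) continue;
      double s = std::sqrt(s2);
      double qq = KE * qv[i] * qv[j];
      double erfcv = std::erfc(ewAlpha * s);
      energy += qq * erfcv / s;
      double dudr = -qq * (erfcv / s2 + 2.0 * ewAlpha / sqrtPi *
                    std::exp(-ewAlpha * ewAlpha * s2) / s);
      double c = -dudr / s;
      double fij[3];
      for (int d = 0; d < 3; ++d) {
        fij[d] = c * rij[d];
        f[3 * i + d] += fij[d];
        f[3 * j + d] -= fij[d];
      }
      addVir(vir, rij, fij);
    }
  int km[3] = {ewKmax[0], ewKmax[1], ewKmax[2]};
  ewaldRecip(r, qv, box, ewAlpha, km, ewKcut2, f, vir, &energy);
  double q2 = 0;
  for (int i = 0; i < n; ++i) q2 += qv[i] * qv[i];
  energy -= KE * ewAlpha / sqrtPi * q2;
  NumericMatrix fo(n, 3), vm(3, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fo(i, d) = f[3 * i + d];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) vm(a, b) = vir[3 * a + b];
  return List::create(_["energy"] = energy, _["forces"] = fo,
                      _["virial"] = vm);
}

// ---------------------------------------------------------------------------
// MD driver: NVE (0), Nose-Hoover NVT (1), NVT + isotropic cell dynamics (2).

// [[Rcpp::export]]
List cppRunMD(NumericMatrix posA, NumericMatrix velA, NumericVector boxA,
              List ff, double ewAlpha, IntegerVector ewKmax, double ewKcut2,
              double rcut,
              bool lrcE, bool lrcP, bool interact,
              int integrator, double dt, int steps,
              double T0, double tauT, double P0bar, double tauP,
              bool rigid, int sampleEvery, int snapshotEvery) {
  const int nphys = posA.nrow();
  const int nmol = nphys / 3;
  double box[3] = {boxA[0], boxA[1], boxA[2]};
  FF p = parseFF(ff);
  if (rigid == p.flexible)
    stop("constraint flag inconsistent with force-field variant");
  std::vector<double> r(3 * nphys), v(3 * nphys);
  for (int i = 0; i < nphys; ++i)
    for (int d = 0; d < 3; ++d) {
      r[3 * i + d] = posA(i, d);
      v[3 * i + d] = velA(i, d);
    }
  std::vector<double> mass(nphys);
  for (int m = 0; m < nmol; ++m) {
    mass[3 * m] = MASS_O;
    mass[3 * m + 1] = mass[3 * m + 2] = MASS_H;
  }
  Constraints con;
  if (rigid) {
    double dHH = 2.0 * p.re * std::sin(p.thetaE / 2.0);
    con.dOH2 = p.re * p.re;
    con.dHH2 = dHH * dHH;
    rattleVelocities(r, v, con, nmol);
  }
  const int ndf = rigid ? (6 * nmol - 3) : (9 * nmol - 3);
  const double Pconv = 4184.0 / 6.02214076e23 / 1e-30 / 1e5; // kcal/mol/A^3 -> bar
  const double P0 = P0bar / Pconv;

  // thermostat / barostat state
  double vxi = 0.0;
  const double twoPi2 = 4.0 * M_PI * M_PI;
  double Q = ndf * KB * std::max(T0, 1.0) * tauT * tauT / twoPi2;
  double veps = 0.0;
  double W = (ndf + 3) * KB * std::max(T0, 1.0) * tauP * tauP / twoPi2;

  std::vector<double> f;
  EnergyAcc E;
  double virMol[9];
  int km[3] = {ewKmax[0], ewKmax[1], ewKmax[2]};
  auto forces = [&]() {
    E = EnergyAcc();
    waterForces(r, box, p, ewAlpha, km, ewKcut2, rcut, lrcE, lrcP, interact,
                f, E, virMol);
  };
  auto kinetic = [&]() {
    double K = 0;
    for (int i = 0; i < nphys; ++i)
      for (int d = 0; d < 3; ++d)
        K += 0.5 * mass[i] * v[3 * i + d] * v[3 * i + d];
    return K / FCONV; // kcal/mol
  };
  auto nhHalf = [&](double hdt) {
    if (T0 <= 0) return;
    double K = kinetic();
    double G = (2.0 * K - ndf * KB * T0) / Q;
    vxi += G * hdt / 2.0;
    double s = std::exp(-vxi * hdt);
    for (auto& x : v) x *= s;
    K *= s * s;
    G = (2.0 * K - ndf * KB * T0) / Q;
    vxi += G * hdt / 2.0;
  };
  auto molPressure = [&](double Pab[9]) {
    // kinetic (COM) + molecular virial, in kcal/mol/A^3
    double Vbox = box[0] * box[1] * box[2];
    double kin[9] = {0,0,0,0,0,0,0,0,0};
    const double Mtot = MASS_O + 2 * MASS_H;
    for (int m = 0; m < nmol; ++m) {
      double vc[3] = {0, 0, 0};
      for (int s = 0; s < 3; ++s)
        for (int d = 0; d < 3; ++d)
          vc[d] += mass[3 * m + s] * v[3 * (3 * m + s) + d] / Mtot;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          kin[3 * a + b] += Mtot * vc[a] * vc[b] / FCONV;
    }
    for (int k = 0; k < 9; ++k) Pab[k] = (kin[k] + virMol[k]) / Vbox;
  };

  forces();
  const int nSamp = steps / sampleEvery + 1;
  NumericMatrix series(nSamp, 20);
  List snaps;
  std::vector<double> r0(3 * nphys);
  int isamp = 0;
  auto sample = [&](int step) {
    double K = kinetic();
    double Vbox = box[0] * box[1] * box[2];
    double Pab[9];
    molPressure(Pab);
    double Etot = E.total() + K;
    double Mdip[3] = {0, 0, 0};
    for (int m = 0; m < nmol; ++m) {
      const double* O = &r[9 * m];
      const double* H1 = &r[9 * m + 3];
      const double* H2 = &r[9 * m + 6];
      for (int d = 0; d < 3; ++d) {
        double rmd = O[d] + p.a * ((H1[d] - O[d]) + (H2[d] - O[d]));
        Mdip[d] += p.qH * (H1[d] + H2[d]) + p.qM * rmd;
      }
    }
    double row[20] = {step * dt, E.total(), K, Etot,
                      Etot + P0 * Vbox,
                      (ndf > 0 ? 2.0 * K / (ndf * KB) : 0.0),
                      Vbox, (Pab[0] + Pab[4] + Pab[8]) / 3.0 * Pconv,
                      Pab[0] * Pconv, Pab[4] * Pconv, Pab[8] * Pconv,
                      Pab[1] * Pconv, Pab[2] * Pconv, Pab[5] * Pconv,
                      box[0], box[1], box[2], Mdip[0], Mdip[1], Mdip[2]};
    for (int k = 0; k < 20; ++k) series(isamp, k) = row[k];
    ++isamp;
  };
  sample(0);

  for (int step = 1; step <= steps; ++step) {
    if (integrator >= 1) nhHalf(dt);
    if (integrator == 2) {
      double Pab[9];
      molPressure(Pab);
      double Pm = (Pab[0] + Pab[4] + Pab[8]) / 3.0;
      double Vbox = box[0] * box[1] * box[2];
      veps = veps * std::exp(-0.5 * dt / tauP) +
             0.5 * dt * 3.0 * Vbox * (Pm - P0) / W;
    }
    // half kick
    for (int i = 0; i < nphys; ++i)
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] += 0.5 * dt * f[3 * i + d] * FCONV / mass[i];
    // drift
    r0 = r;
    for (int i = 0; i < 3 * nphys; ++i) r[i] += dt * v[i];
    if (integrator == 2 && veps != 0.0) {
      double lam = std::exp(veps * dt);
      for (int d = 0; d < 3; ++d) box[d] *= lam;
      // molecular (COM) scaling: internal geometry untouched; velocities
      // are left to the thermostat (no direct kinetic coupling)
      const double Mtot = MASS_O + 2 * MASS_H;
      for (int m = 0; m < nmol; ++m) {
        double com[3] = {0, 0, 0};
        for (int s = 0; s < 3; ++s)
          for (int d = 0; d < 3; ++d)
            com[d] += mass[3 * m + s] * r[3 * (3 * m + s) + d] / Mtot;
        for (int s = 0; s < 3; ++s)
          for (int d = 0; d < 3; ++d)
            r[3 * (3 * m + s) + d] += (lam - 1.0) * com[d];
      }
      if (box[0] < 2.0 * rcut || box[1] < 2.0 * rcut || box[2] < 2.0 * rcut)
        stop("box shrank below twice the cutoff during NPT");
    }
    if (rigid) shakeStep(r, v, r0, dt, con, nmol);
    forces();
    for (int i = 0; i < nphys; ++i)
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] += 0.5 * dt * f[3 * i + d] * FCONV / mass[i];
    if (rigid) rattleVelocities(r, v, con, nmol);
    if (integrator == 2) {
      double Pab[9];
      molPressure(Pab);
      double Pm = (Pab[0] + Pab[4] + Pab[8]) / 3.0;
      double Vbox = box[0] * box[1] * box[2];
      veps = veps * std::exp(-0.5 * dt / tauP) +
             0.5 * dt * 3.0 * Vbox * (Pm - P0) / W;
    }
    if (integrator >= 1) nhHalf(dt);
    if (step % sampleEvery == 0) sample(step);
    if (snapshotEvery > 0 && step % snapshotEvery == 0) {
      NumericMatrix rs(nphys, 3), vs(nphys, 3);
      for (int i = 0; i < nphys; ++i)
        for (int d = 0; d < 3; ++d) {
          rs(i, d) = r[3 * i + d];
          vs(i, d) = v[3 * i + d];
        }
      snaps.push_back(List::create(_["positions"] = rs, _["velocities"] = vs,
                                   _["box"] = NumericVector::create(
                                     box[0], box[1], box[2]),
                                   _["time"] = step * dt));
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix rOut(nphys, 3), vOut(nphys, 3);
  for (int i = 0; i < nphys; ++i)
    for (int d = 0; d < 3; ++d) {
      rOut(i, d) = r[3 * i + d];
      vOut(i, d) = v[3 * i + d];
    }
  colnames(series) = CharacterVector::create(
    "time", "epot", "ekin", "etot", "enthalpy", "temperature", "volume",
    "pressure", "Pxx", "Pyy", "Pzz", "Pxy", "Pxz", "Pyz",
    "boxX", "boxY", "boxZ", "Mx", "My", "Mz");
  return List::create(_["series"] = series, _["snapshots"] = snaps,
                      _["positions"] = rOut, _["velocities"] = vOut,
                      _["box"] = NumericVector::create(box[0], box[1], box[2]));
}

// Apply the constraint projection once to a state (positions already
// satisfying geometry are left untouched; velocity components along the
// constraints are removed).
// [[Rcpp::export]]
List cppConstrain(NumericMatrix posA, NumericMatrix velA, double re,
                  double thetaE) {
  int nphys = posA.nrow(), nmol = nphys / 3;
  std::vector<double> r(3 * nphys), v(3 * nphys), r0(3 * nphys);
  for (int i = 0; i < nphys; ++i)
    for (int d = 0; d < 3; ++d) {
      r[3 * i + d] = r0[3 * i + d] = posA(i, d);
      v[3 * i + d] = velA(i, d);
    }
  Constraints con;
  double dHH = 2.0 * re * std::sin(thetaE / 2.0);
  con.dOH2 = re * re;
  con.dHH2 = dHH * dHH;
  // iterative projection of positions onto the constraint manifold
  shakeStep(r, v, r0, 1.0, con, nmol);
  rattleVelocities(r, v, con, nmol);
  NumericMatrix rOut(nphys, 3), vOut(nphys, 3);
  for (int i = 0; i < nphys; ++i)
    for (int d = 0; d < 3; ++d) {
      rOut(i, d) = r[3 * i + d];
      vOut(i, d) = v[3 * i + d];
    }
  return List::create(_["positions"] = rOut, _["velocities"] = vOut);
}
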