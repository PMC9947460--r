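// Axisymmetric finite-element kernels: nearly incompressible neo-Hookean
// hyperelasticity with multiplicative hygroscopic swelling, follower pressure
// boundary loads, and node-to-segment penalty contact.
//
// Unit conventions: lengths mm, stresses Pa, assembled forces uN
// (1 Pa * mm^2 = 1 uN). Axisymmetric measure 2*pi*r dr dz is included, so
// nodal forces are full ring resultants.
//
// Deformation gradient components are carried as a 5-vector
//   f = (F_rr, F_rz, F_zr, F_zz, F_tt)
// where F_tt = 1 + u_r / r is the hoop stretch.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int IA[5] = {0, 0, 1, 1, 2}; // row index of component a
static const int JA[5] = {0, 1, 0, 1, 2}; // column index of component a

// Energy density W, stress P (dW/dF) and tangent A (d2W/dF dF) in 5-component
// form. W = JH * ( mu/2 (J^{-2/3} I1 - 3) + kappa/2 * ln(J/JH)^2 ).
// Returns false on non-positive Jacobian.
static bool nh_eval(const double f[5], double mu, double kappa, double JH,
                    double &W, double P[5], double A[25], bool want_A) {
  const double d2 = f[0] * f[3] - f[1] * f[2];
  const double J = f[4] * d2;
  if (!(J > 0.0) || !(f[4] > 0.0)) return false;
  double Finv[3][3] = {{0}};
  Finv[0][0] = f[3] / d2;  Finv[0][1] = -f[1] / d2;
  Finv[1][0] = -f[2] / d2; Finv[1][1] = f[0] / d2;
  Finv[2][2] = 1.0 / f[4];
  double g[5];
  for (int a = 0; a < 5; ++a) g[a] = Finv[JA[a]][IA[a]]; // (F^{-T})_{iJ}
  const double I1 = f[0] * f[0] + f[1] * f[1] + f[2] * f[2] + f[3] * f[3] + f[4] * f[4];
  const double c = std::pow(J, -2.0 / 3.0);
  const double L = std::log(J / JH);
  W = JH * (0.5 * mu * (c * I1 - 3.0) + 0.5 * kappa * L * L);
  for (int a = 0; a < 5; ++a)
    P[a] = JH * (mu * c * (f[a] - I1 / 3.0 * g[a]) + kappa * L * g[a]);
  if (want_A) {
    for (int a = 0; a < 5; ++a) {
      for (int b = 0; b < 5; ++b) {
        const double Gab = -Finv[JA[a]][IA[b]] * Finv[JA[b]][IA[a]];
        double v = mu * c * (-(2.0 / 3.0) * (g[b] * f[a] + f[b] * g[a])
                             + (2.0 / 9.0) * I1 * g[a] * g[b]
                             + ((a == b) ? 1.0 : 0.0)
                             - I1 / 3.0 * Gab)
                 + kappa * (g[a] * g[b] + L * Gab);
        A[a * 5 + b] = JH * v;
      }
    }
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = "nh_point")]]
List nh_point(NumericVector f, double mu, double kappa, double JH) {
  if (f.size() != 5) stop("nh_point: f must have length 5");
  double fl[5];
  for (int a = 0; a < 5; ++a) fl[a] = f[a];
  double W, P[5], A[25];
  if (!nh_eval(fl, mu, kappa, JH, W, P, A, true))
    stop("nh_point: non-positive Jacobian");
  NumericVector Pv(5);
  NumericMatrix Av(5, 5);
  for (int a = 0; a < 5; ++a) {
    Pv[a] = P[a];
    for (int b = 0; b < 5; ++b) Av(a, b) = A[a * 5 + b];
  }
  return List::create(_["W"] = W, _["P"] = Pv, _["A"] = Av);
}

// Assemble internal residual and tangent triplets for one quadrature rule.
// basis: list(phi = nen x nq, dxi = nen x nq, deta = nen x nq, w = nq)
// mat: per-element rows already expanded (E x 3): mu, kappa, JH
static bool asm_rule(const NumericMatrix &nodes, const IntegerMatrix &elems,
                     const NumericMatrix &mat, const NumericVector &u,
                     const List &basis, std::vector<double> &R,
                     std::vector<int> &ti, std::vector<int> &tj,
                     std::vector<double> &tx, double &Wtot, int &badElem) {
  const NumericMatrix phi = basis["phi"], dxi = basis["dxi"], deta = basis["deta"];
  const NumericVector wq = basis["w"];
  const int nen = phi.nrow(), nq = phi.ncol(), E = elems.ncol();
  const double TWO_PI = 2.0 * M_PI;
  std::vector<double> Xr(nen), Xz(nen), Ur(nen), Uz(nen), dNr(nen), dNz(nen);
  for (int e = 0; e < E; ++e) {
    const double mu = mat(e, 0), kappa = mat(e, 1), JH = mat(e, 2);
    for (int n = 0; n < nen; ++n) {
      const int g = elems(n, e) - 1;
      Xr[n] = nodes(g, 0); Xz[n] = nodes(g, 1);
      Ur[n] = u[2 * g]; Uz[n] = u[2 * g + 1];
    }
    std::vector<double> Ke(4 * nen * nen, 0.0), Re(2 * nen, 0.0);
    for (int q = 0; q < nq; ++q) {
      double j11 = 0, j12 = 0, j21 = 0, j22 = 0, rref = 0, urq = 0;
      double Fc[5] = {1, 0, 0, 1, 1};
      for (int n = 0; n < nen; ++n) {
        j11 += dxi(n, q) * Xr[n];  j12 += dxi(n, q) * Xz[n];
        j21 += deta(n, q) * Xr[n]; j22 += deta(n, q) * Xz[n];
        rref += phi(n, q) * Xr[n];
        urq += phi(n, q) * Ur[n];
      }
      const double detJ = j11 * j22 - j12 * j21;
      if (!(detJ > 0.0) || !(rref > 0.0)) { badElem = e + 1; return false; }
      const double i11 = j22 / detJ, i12 = -j12 / detJ,
                   i21 = -j21 / detJ, i22 = j11 / detJ;
      for (int n = 0; n < nen; ++n) {
        dNr[n] = dxi(n, q) * i11 + deta(n, q) * i12;
        dNz[n] = dxi(n, q) * i21 + deta(n, q) * i22;
        Fc[0] += dNr[n] * Ur[n];
        Fc[1] += dNz[n] * Ur[n];
        Fc[2] += dNr[n] * Uz[n];
        Fc[3] += dNz[n] * Uz[n];
      }
      Fc[4] = 1.0 + urq / rref;
      double W, P[5], A[25];
      if (!nh_eval(Fc, mu, kappa, JH, W, P, A, true)) { badElem = e + 1; return false; }
      const double wgt = wq[q] * detJ * TWO_PI * rref;
      Wtot += wgt * W;
      // B vectors: for node n, dof r: (dNr, dNz, 0, 0, phi/r); dof z: (0,0,dNr,dNz,0)
      for (int n = 0; n < nen; ++n) {
        const double Br[5] = {dNr[n], dNz[n], 0.0, 0.0, phi(n, q) / rref};
        const double Bz[5] = {0.0, 0.0, dNr[n], dNz[n], 0.0};
        double rn = 0, zn = 0;
        for (int a = 0; a < 5; ++a) { rn += P[a] * Br[a]; zn += P[a] * Bz[a]; }
        Re[2 * n] += wgt * rn;
        Re[2 * n + 1] += wgt * zn;
        // AB products for this node (columns of K)
        double ABr[5], ABz[5];
        for (int a = 0; a < 5; ++a) {
          double sr = 0, sz = 0;
          for (int b = 0; b < 5; ++b) {
            sr += A[a * 5 + b] * Br[b];
            sz += A[a * 5 + b] * Bz[b];
          }
          ABr[a] = sr; ABz[a] = sz;
        }
        for (int m = 0; m < nen; ++m) {
          const double Br2[5] = {dNr[m], dNz[m], 0.0, 0.0, phi(m, q) / rref};
          const double Bz2[5] = {0.0, 0.0, dNr[m], dNz[m], 0.0};
          double krr = 0, krz = 0, kzr = 0, kzz = 0;
          for (int a = 0; a < 5; ++a) {
            krr += Br2[a] * ABr[a];
            krz += Br2[a] * ABz[a];
            kzr += Bz2[a] * ABr[a];
            kzz += Bz2[a] * ABz[a];
          }
          Ke[(2 * m) * 2 * nen + 2 * n] += wgt * krr;
          Ke[(2 * m) * 2 * nen + 2 * n + 1] += wgt * krz;
          Ke[(2 * m + 1) * 2 * nen + 2 * n] += wgt * kzr;
          Ke[(2 * m + 1) * 2 * nen + 2 * n + 1] += wgt * kzz;
        }
      }
    }
    for (int n = 0; n < nen; ++n) {
      const int gn = elems(n, e) - 1;
      R[2 * gn] += Re[2 * n];
      R[2 * gn + 1] += Re[2 * n + 1];
      for (int m = 0; m < nen; ++m) {
        const int gm = elems(m, e) - 1;
        for (int dn = 0; dn < 2; ++dn)
          for (int dm = 0; dm < 2; ++dm) {
            const double v = Ke[(2 * m + dm) * 2 * nen + 2 * n + dn];
            if (v != 0.0) {
              ti.push_back(2 * gn + dn + 1);
              tj.push_back(2 * gm + dm + 1);
              tx.push_back(v);
            }
          }
      }
    }
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = "asm_volume_cpp")]]
List asm_volume_cpp(NumericMatrix nodes, IntegerMatrix elems,
                    NumericMatrix mat_dev, NumericMatrix mat_vol,
                    NumericVector u, List basis_dev, List basis_vol) {
  const int N = nodes.nrow();
  std::vector<double> R(2 * N, 0.0);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(elems.ncol() * 200);
  double Wtot = 0.0;
  int badElem = 0;
  bool ok = asm_rule(nodes, elems, mat_dev, u, basis_dev, R, ti, tj, tx, Wtot, badElem);
  if (ok)
    ok = asm_rule(nodes, elems, mat_vol, u, basis_vol, R, ti, tj, tx, Wtot, badElem);
  NumericVector Rv(R.begin(), R.end());
  return List::create(_["ok"] = ok, _["bad_elem"] = badElem, _["R"] = Rv,
                      _["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()),
                      _["W"] = Wtot);
}

//' @noRd
// [[Rcpp::export(name = "elem_fields_cpp")]]
NumericMatrix elem_fields_cpp(NumericMatrix nodes, IntegerMatrix elems,
                              NumericMatrix mat, NumericVector u, List basis) {
  const NumericMatrix phi = basis["phi"], dxi = basis["dxi"], deta = basis["deta"];
  const NumericVector wq = basis["w"];
  const int nen = phi.nrow(), nq = phi.ncol(), E = elems.ncol();
  NumericMatrix out(E, 5); // vol_ref(mm^3), J, Je, hydro(Pa), W(Pa)
  colnames(out) = CharacterVector::create("vol", "J", "Je", "hydro", "W");
  const double TWO_PI = 2.0 * M_PI;
  for (int e = 0; e < E; ++e) {
    const double mu = mat(e, 0), kappa = mat(e, 1), JH = mat(e, 2);
    double vol = 0, Jm = 0, Jem = 0, hyd = 0, Wm = 0;
    for (int q = 0; q < nq; ++q) {
      double j11 = 0, j12 = 0, j21 = 0, j22 = 0, rref = 0, urq = 0;
      double Fc[5] = {1, 0, 0, 1, 1};
      std::vector<double> dNr(nen), dNz(nen);
      for (int n = 0; n < nen; ++n) {
        const int g = elems(n, e) - 1;
        j11 += dxi(n, q) * nodes(g, 0);  j12 += dxi(n, q) * nodes(g, 1);
        j21 += deta(n, q) * nodes(g, 0); j22 += deta(n, q) * nodes(g, 1);
        rref += phi(n, q) * nodes(g, 0);
        urq += phi(n, q) * u[2 * g];
      }
      const double detJ = j11 * j22 - j12 * j21;
      const double i11 = j22 / detJ, i12 = -j12 / detJ,
                   i21 = -j21 / detJ, i22 = j11 / detJ;
      for (int n = 0; n < nen; ++n) {
        const int g = elems(n, e) - 1;
        const double dr = dxi(n, q) * i11 + deta(n, q) * i12;
        const double dz = dxi(n, q) * i21 + deta(n, q) * i22;
        Fc[0] += dr * u[2 * g];
        Fc[1] += dz * u[2 * g];
        Fc[2] += dr * u[2 * g + 1];
        Fc[3] += dz * u[2 * g + 1];
      }
      Fc[4] = 1.0 + urq / rref;
      double W, P[5], A[25];
      if (!nh_eval(Fc, mu, kappa, JH, W, P, A, false)) {
        out(e, 1) = NA_REAL;
        continue;
      }
      const double J = Fc[4] * (Fc[0] * Fc[3] - Fc[1] * Fc[2]);
      // Cauchy hydrostatic: tr(P F^T)/(3J)
      double trPF = 0;
      for (int a = 0; a < 5; ++a) trPF += P[a] * Fc[a];
      const double wgt = wq[q] * detJ * TWO_PI * rref;
      vol += wgt;
      Jm += wgt * J;
      Jem += wgt * J / JH;
      hyd += wgt * trPF / (3.0 * J);
      Wm += wgt * W;
    }
    out(e, 0) = vol;
    out(e, 1) = Jm / vol;
    out(e, 2) = Jem / vol;
    out(e, 3) = hyd / vol;
    out(e, 4) = Wm / vol;
  }
  return out;
}

// Mean-dilatation (B-bar) volumetric penalty: one constraint per element.
// W_e = JH * V0 * kappa/2 * ln(Jbar/JH)^2 with Jbar = (1/V0) int J dV0.
// Removes volumetric locking of the quadratic triangles and enforces exact
// discrete volume bookkeeping for the near-fluid tissues.
//' @noRd
// [[Rcpp::export(name = "asm_meandil_cpp")]]
List asm_meandil_cpp(NumericMatrix nodes, IntegerMatrix elems,
                     NumericMatrix mat, NumericVector u, List basis) {
  const NumericMatrix phi = basis["phi"], dxi = basis["dxi"], deta = basis["deta"];
  const NumericVector wq = basis["w"];
  const int nen = phi.nrow(), nq = phi.ncol(), E = elems.ncol();
  const int N = nodes.nrow();
  const double TWO_PI = 2.0 * M_PI;
  NumericVector R(2 * N), Jbar_out(E);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  double Wtot = 0.0;
  std::vector<double> Xr(nen), Xz(nen), Ur(nen), Uz(nen), dNr(nen), dNz(nen);
  std::vector<double> bvec(2 * nen), Kgeo(4 * nen * nen);
  int badElem = 0;
  for (int e = 0; e < E; ++e) {
    const double kappa = mat(e, 0), JH = mat(e, 1);
    for (int n = 0; n < nen; ++n) {
      const int g = elems(n, e) - 1;
      Xr[n] = nodes(g, 0); Xz[n] = nodes(g, 1);
      Ur[n] = u[2 * g]; Uz[n] = u[2 * g + 1];
    }
    double V0 = 0, Jint = 0;
    std::fill(bvec.begin(), bvec.end(), 0.0);
    std::fill(Kgeo.begin(), Kgeo.end(), 0.0);
    bool bad = false;
    for (int q = 0; q < nq && !bad; ++q) {
      double j11 = 0, j12 = 0, j21 = 0, j22 = 0, rref = 0, urq = 0;
      double Fc[5] = {1, 0, 0, 1, 1};
      for (int n = 0; n < nen; ++n) {
        j11 += dxi(n, q) * Xr[n];  j12 += dxi(n, q) * Xz[n];
        j21 += deta(n, q) * Xr[n]; j22 += deta(n, q) * Xz[n];
        rref += phi(n, q) * Xr[n];
        urq += phi(n, q) * Ur[n];
      }
      const double detJ = j11 * j22 - j12 * j21;
      if (!(detJ > 0.0) || !(rref > 0.0)) { bad = true; break; }
      const double i11 = j22 / detJ, i12 = -j12 / detJ,
                   i21 = -j21 / detJ, i22 = j11 / detJ;
      for (int n = 0; n < nen; ++n) {
        dNr[n] = dxi(n, q) * i11 + deta(n, q) * i12;
        dNz[n] = dxi(n, q) * i21 + deta(n, q) * i22;
        Fc[0] += dNr[n] * Ur[n];
        Fc[1] += dNz[n] * Ur[n];
        Fc[2] += dNr[n] * Uz[n];
        Fc[3] += dNz[n] * Uz[n];
      }
      Fc[4] = 1.0 + urq / rref;
      const double d2 = Fc[0] * Fc[3] - Fc[1] * Fc[2];
      const double J = Fc[4] * d2;
      if (!(J > 0.0)) { bad = true; break; }
      double g5[5];
      g5[0] = Fc[3] / d2; g5[1] = -Fc[2] / d2;
      g5[2] = -Fc[1] / d2; g5[3] = Fc[0] / d2; g5[4] = 1.0 / Fc[4];
      double Finv[3][3] = {{0}};
      Finv[0][0] = Fc[3] / d2;  Finv[0][1] = -Fc[1] / d2;
      Finv[1][0] = -Fc[2] / d2; Finv[1][1] = Fc[0] / d2;
      Finv[2][2] = 1.0 / Fc[4];
      const double wgt = wq[q] * detJ * TWO_PI * rref;
      V0 += wgt;
      Jint += wgt * J;
      // per-dof b = int J B^T g; geometric part int J (B^T g g^T B + B^T G B)
      std::vector<double> Bg(2 * nen);
      for (int n = 0; n < nen; ++n) {
        const double Br[5] = {dNr[n], dNz[n], 0.0, 0.0, phi(n, q) / rref};
        const double Bz[5] = {0.0, 0.0, dNr[n], dNz[n], 0.0};
        double sr = 0, sz = 0;
        for (int a = 0; a < 5; ++a) { sr += Br[a] * g5[a]; sz += Bz[a] * g5[a]; }
        Bg[2 * n] = sr; Bg[2 * n + 1] = sz;
        bvec[2 * n] += wgt * J * sr;
        bvec[2 * n + 1] += wgt * J * sz;
      }
      // B^T G B with G_ab = -Finv[Ja,ib] Finv[Jb,ia]
      for (int n = 0; n < nen; ++n) {
        const double Bn[2][5] = {{dNr[n], dNz[n], 0, 0, phi(n, q) / rref},
                                 {0, 0, dNr[n], dNz[n], 0}};
        for (int m2 = 0; m2 < nen; ++m2) {
          const double Bm[2][5] = {{dNr[m2], dNz[m2], 0, 0, phi(m2, q) / rref},
                                   {0, 0, dNr[m2], dNz[m2], 0}};
          for (int dn = 0; dn < 2; ++dn)
            for (int dm = 0; dm < 2; ++dm) {
              double s = Bg[2 * n + dn] * Bg[2 * m2 + dm];
              for (int a = 0; a < 5; ++a)
                for (int b = 0; b < 5; ++b) {
                  if (Bn[dn][a] == 0.0 || Bm[dm][b] == 0.0) continue;
                  const double Gab = -Finv[JA[a]][IA[b]] * Finv[JA[b]][IA[a]];
                  s += Bn[dn][a] * Gab * Bm[dm][b];
                }
              Kgeo[(2 * m2 + dm) * 2 * nen + 2 * n + dn] += wgt * J * s;
            }
        }
      }
    }
    if (bad) { badElem = e + 1; break; }
    const double Jb = Jint / V0;
    Jbar_out[e] = Jb;
    const double L = std::log(Jb / JH);
    Wtot += JH * V0 * 0.5 * kappa * L * L;
    const double C1 = JH * kappa * L / Jb;          // dW/dJbar * V0 scaling
    const double C2 = JH * kappa * (1.0 - L) / (Jb * Jb);
    for (int n = 0; n < 2 * nen; ++n) {
      const int gn = 2 * (elems(n / 2, e) - 1) + (n % 2);
      R[gn] += C1 * bvec[n] / 1.0; // (1/V0)*b * C'(Jbar)*V0 = C1 * b
    }
    for (int n = 0; n < 2 * nen; ++n) {
      const int gn = 2 * (elems(n / 2, e) - 1) + (n % 2);
      for (int m2 = 0; m2 < 2 * nen; ++m2) {
        const int gm = 2 * (elems(m2 / 2, e) - 1) + (m2 % 2);
        const double v = C2 * bvec[n] * bvec[m2] / V0 +
                         C1 * Kgeo[m2 * 2 * nen + n];
        if (v != 0.0) {
          ti.push_back(gn + 1);
          tj.push_back(gm + 1);
          tx.push_back(v);
        }
      }
    }
  }
  return List::create(_["ok"] = badElem == 0, _["bad_elem"] = badElem,
                      _["R"] = R,
                      _["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()),
                      _["W"] = Wtot, _["Jbar"] = Jbar_out);
}

//' @noRd
// [[Rcpp::export(name = "asm_mixedq_cpp")]]
List asm_mixedq_cpp(NumericMatrix nodes, IntegerMatrix elems,
                     NumericMatrix mat, NumericVector u, NumericVector pvec,
                     List basis) {
  const NumericMatrix phi = basis["phi"], dxi = basis["dxi"], deta = basis["deta"];
  const NumericVector wq = basis["w"];
  const int nen = phi.nrow(), nq = phi.ncol(), E = elems.ncol();
  const int N = nodes.nrow();
  const double TWO_PI = 2.0 * M_PI;
  NumericVector R(2 * N), Rp(E), V0out(E), Jbar_out(E);
  NumericMatrix Bout(2 * nen > 0 ? 2 * nen : 1, E);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  double Wtot = 0.0;
  std::vector<double> Xr(nen), Xz(nen), Ur(nen), Uz(nen), dNr(nen), dNz(nen);
  std::vector<double> bvec(2 * nen), Kgeo(4 * nen * nen);
  int badElem = 0;
  for (int e = 0; e < E; ++e) {
    const double kappa = mat(e, 0), JH = mat(e, 1);
    for (int n = 0; n < nen; ++n) {
      const int g = elems(n, e) - 1;
      Xr[n] = nodes(g, 0); Xz[n] = nodes(g, 1);
      Ur[n] = u[2 * g]; Uz[n] = u[2 * g + 1];
    }
    double V0 = 0, Jint = 0;
    std::fill(bvec.begin(), bvec.end(), 0.0);
    std::fill(Kgeo.begin(), Kgeo.end(), 0.0);
    bool bad = false;
    for (int q = 0; q < nq && !bad; ++q) {
      double j11 = 0, j12 = 0, j21 = 0, j22 = 0, rref = 0, urq = 0;
      double Fc[5] = {1, 0, 0, 1, 1};
      for (int n = 0; n < nen; ++n) {
        j11 += dxi(n, q) * Xr[n];  j12 += dxi(n, q) * Xz[n];
        j21 += deta(n, q) * Xr[n]; j22 += deta(n, q) * Xz[n];
        rref += phi(n, q) * Xr[n];
        urq += phi(n, q) * Ur[n];
      }
      const double detJ = j11 * j22 - j12 * j21;
      if (!(detJ > 0.0) || !(rref > 0.0)) { bad = true; break; }
      const double i11 = j22 / detJ, i12 = -j12 / detJ,
                   i21 = -j21 / detJ, i22 = j11 / detJ;
      for (int n = 0; n < nen; ++n) {
        dNr[n] = dxi(n, q) * i11 + deta(n, q) * i12;
        dNz[n] = dxi(n, q) * i21 + deta(n, q) * i22;
        Fc[0] += dNr[n] * Ur[n];
        Fc[1] += dNz[n] * Ur[n];
        Fc[2] += dNr[n] * Uz[n];
        Fc[3] += dNz[n] * Uz[n];
      }
      Fc[4] = 1.0 + urq / rref;
      const double d2 = Fc[0] * Fc[3] - Fc[1] * Fc[2];
      const double J = Fc[4] * d2;
      if (!(J > 0.0)) { bad = true; break; }
      double g5[5];
      g5[0] = Fc[3] / d2; g5[1] = -Fc[2] / d2;
      g5[2] = -Fc[1] / d2; g5[3] = Fc[0] / d2; g5[4] = 1.0 / Fc[4];
      double Finv[3][3] = {{0}};
      Finv[0][0] = Fc[3] / d2;  Finv[0][1] = -Fc[1] / d2;
      Finv[1][0] = -Fc[2] / d2; Finv[1][1] = Fc[0] / d2;
      Finv[2][2] = 1.0 / Fc[4];
      const double wgt = wq[q] * detJ * TWO_PI * rref;
      V0 += wgt;
      Jint += wgt * J;
      // per-dof b = int J B^T g; geometric part int J (B^T g g^T B + B^T G B)
      std::vector<double> Bg(2 * nen);
      for (int n = 0; n < nen; ++n) {
        const double Br[5] = {dNr[n], dNz[n], 0.0, 0.0, phi(n, q) / rref};
        const double Bz[5] = {0.0, 0.0, dNr[n], dNz[n], 0.0};
        double sr = 0, sz = 0;
        for (int a = 0; a < 5; ++a) { sr += Br[a] * g5[a]; sz += Bz[a] * g5[a]; }
        Bg[2 * n] = sr; Bg[2 * n + 1] = sz;
        bvec[2 * n] += wgt * J * sr;
        bvec[2 * n + 1] += wgt * J * sz;
      }
      // B^T G B with G_ab = -Finv[Ja,ib] Finv[Jb,ia]
      for (int n = 0; n < nen; ++n) {
        const double Bn[2][5] = {{dNr[n], dNz[n], 0, 0, phi(n, q) / rref},
                                 {0, 0, dNr[n], dNz[n], 0}};
        for (int m2 = 0; m2 < nen; ++m2) {
          const double Bm[2][5] = {{dNr[m2], dNz[m2], 0, 0, phi(m2, q) / rref},
                                   {0, 0, dNr[m2], dNz[m2], 0}};
          for (int dn = 0; dn < 2; ++dn)
            for (int dm = 0; dm < 2; ++dm) {
              double s = Bg[2 * n + dn] * Bg[2 * m2 + dm];
              for (int a = 0; a < 5; ++a)
                for (int b = 0; b < 5; ++b) {
                  if (Bn[dn][a] == 0.0 || Bm[dm][b] == 0.0) continue;
                  const double Gab = -Finv[JA[a]][IA[b]] * Finv[JA[b]][IA[a]];
                  s += Bn[dn][a] * Gab * Bm[dm][b];
                }
              Kgeo[(2 * m2 + dm) * 2 * nen + 2 * n + dn] += wgt * J * s;
            }
        }
      }
    }
    if (bad) { badElem = e + 1; break; }
    const double Jb = Jint / V0;
    const double pe = pvec[e];
    V0out[e] = V0;
    Jbar_out[e] = Jb;
    Rp[e] = V0 * (Jb - JH) / JH - pe * V0 / kappa;
    const double cst = (Jb - JH) / JH;
    Wtot += 0.5 * kappa * cst * cst * V0;
    for (int n = 0; n < 2 * nen; ++n) Bout(n, e) = bvec[n];
    const double cp = pe / JH;
    const double cb = kappa / (V0 * JH * JH);
    for (int n = 0; n < 2 * nen; ++n) {
      const int gn = 2 * (elems(n / 2, e) - 1) + (n % 2);
      R[gn] += cp * bvec[n];
      for (int m2 = 0; m2 < 2 * nen; ++m2) {
        const int gm = 2 * (elems(m2 / 2, e) - 1) + (m2 % 2);
        const double v = cb * bvec[n] * bvec[m2] +
                         cp * Kgeo[m2 * 2 * nen + n];
        if (v != 0.0) {
          ti.push_back(gn + 1);
          tj.push_back(gm + 1);
          tx.push_back(v);
        }
      }
    }
  }
  return List::create(_["ok"] = badElem == 0, _["bad_elem"] = badElem,
                      _["Ru"] = R, _["Rp"] = Rp,
                      _["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()),
                      _["W"] = Wtot, _["b"] = Bout, _["V0"] = V0out,
                      _["Jbar"] = Jbar_out);
}


// Mixed displacement-pressure volumetric treatment (perturbed Lagrangian,
// element-wise constant pressure, condensed exactly within each Newton step).
// Element volumes are evaluated EXACTLY through the boundary integral
// V = 2*pi * closed_int (r^2/2) dz over the deformed element boundary: the
// integrand is polynomial in the edge parameter, so the edge Gauss rule is
// exact, interior edges cancel between neighbouring elements, and the total
// volume is fixed by the outer boundary alone (no spurious volumetric modes).
// Per element: constraint c = (V - JH V0)/JH, pressure law p = kappa*c/V0,
// L = sum_e [ p_e c_e - p_e^2 V0/(2 kappa) ].
//' @noRd
// [[Rcpp::export(name = "asm_mixedvol_cpp")]]
List asm_mixedvol_cpp(NumericMatrix nodes, IntegerMatrix elems,
                      NumericMatrix mat, NumericVector u, NumericVector pvec,
                      IntegerMatrix edge_idx, List ebasis) {
  const NumericMatrix phi = ebasis["phi"], dphi = ebasis["dphi"];
  const NumericVector wq = ebasis["w"];
  const int nev = phi.nrow();      // nodes per edge
  const int nq = phi.ncol();
  const int nedge = edge_idx.ncol(); // 3 edges per triangle
  const int nen = elems.nrow(), E = elems.ncol();
  const int N = nodes.nrow();
  const double TWO_PI = 2.0 * M_PI;
  NumericVector Ru(2 * N), Rp(E), V0out(E), Jbar_out(E);
  NumericMatrix Bout(2 * nen, E);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  double Wtot = 0.0;
  std::vector<double> xr(nen), xz(nen), Xr0(nen), Xz0(nen);
  std::vector<double> bvec(2 * nen), Kg(4 * nen * nen);
  int badElem = 0;
  for (int e = 0; e < E; ++e) {
    const double kappa = mat(e, 0), JH = mat(e, 1), pe = pvec[e];
    for (int n = 0; n < nen; ++n) {
      const int g = elems(n, e) - 1;
      Xr0[n] = nodes(g, 0); Xz0[n] = nodes(g, 1);
      xr[n] = Xr0[n] + u[2 * g];
      xz[n] = Xz0[n] + u[2 * g + 1];
    }
    double V = 0, V0 = 0;
    std::fill(bvec.begin(), bvec.end(), 0.0);
    std::fill(Kg.begin(), Kg.end(), 0.0);
    for (int ed = 0; ed < nedge; ++ed) {
      for (int q = 0; q < nq; ++q) {
        double r = 0, dz = 0, r0 = 0, dz0 = 0;
        for (int k = 0; k < nev; ++k) {
          const int l = edge_idx(k, ed) - 1; // local node index
          r += phi(k, q) * xr[l];
          dz += dphi(k, q) * xz[l];
          r0 += phi(k, q) * Xr0[l];
          dz0 += dphi(k, q) * Xz0[l];
        }
        const double w = wq[q] * TWO_PI;
        V += w * 0.5 * r * r * dz;
        V0 += w * 0.5 * r0 * r0 * dz0;
        for (int k = 0; k < nev; ++k) {
          const int l = edge_idx(k, ed) - 1;
          bvec[2 * l] += w * r * phi(k, q) * dz;          // d/dr_l
          bvec[2 * l + 1] += w * 0.5 * r * r * dphi(k, q); // d/dz_l
          for (int k2 = 0; k2 < nev; ++k2) {
            const int l2 = edge_idx(k2, ed) - 1;
            // d2V/(dr dr) and d2V/(dr dz)
            Kg[(2 * l2) * 2 * nen + 2 * l] += w * phi(k, q) * phi(k2, q) * dz;
            Kg[(2 * l2 + 1) * 2 * nen + 2 * l] += w * r * phi(k, q) * dphi(k2, q);
            Kg[(2 * l2) * 2 * nen + 2 * l + 1] += w * r * dphi(k, q) * phi(k2, q);
          }
        }
      }
    }
    if (!(V > 0.0) || !(V0 > 0.0)) { badElem = e + 1; break; }
    V0out[e] = V0;
    Jbar_out[e] = V / V0;
    Rp[e] = (V - JH * V0) / JH - pe * V0 / kappa;
    const double cst = (V - JH * V0) / (JH * V0);
    Wtot += 0.5 * kappa * cst * cst * V0;
    for (int n = 0; n < 2 * nen; ++n) Bout(n, e) = bvec[n];
    const double cp = pe / JH;
    const double cb = kappa / (V0 * JH * JH);
    for (int n = 0; n < 2 * nen; ++n) {
      if (bvec[n] == 0.0) {
        bool rowzero = true;
        for (int m2 = 0; m2 < 2 * nen; ++m2)
          if (Kg[m2 * 2 * nen + n] != 0.0) { rowzero = false; break; }
        if (rowzero) continue;
      }
      const int gn = 2 * (elems(n / 2, e) - 1) + (n % 2);
      Ru[gn] += cp * bvec[n];
      for (int m2 = 0; m2 < 2 * nen; ++m2) {
        const int gm = 2 * (elems(m2 / 2, e) - 1) + (m2 % 2);
        const double v = cb * bvec[n] * bvec[m2] + cp * Kg[m2 * 2 * nen + n];
        if (v != 0.0) {
          ti.push_back(gn + 1);
          tj.push_back(gm + 1);
          tx.push_back(v);
        }
      }
    }
  }
  return List::create(_["ok"] = badElem == 0, _["bad_elem"] = badElem,
                      _["Ru"] = Ru, _["Rp"] = Rp,
                      _["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()),
                      _["W"] = Wtot, _["b"] = Bout, _["V0"] = V0out,
                      _["Jbar"] = Jbar_out);
}

// Follower pressure on boundary edges. Edges traversed with the loaded region
// on the LEFT; outward normal (unnormalised) is (dz, -dr). Traction -p n.
//' @noRd
// [[Rcpp::export(name = "asm_pressure_cpp")]]
List asm_pressure_cpp(NumericMatrix nodes, IntegerMatrix edges, NumericVector u,
                      double p, List ebasis, int ndof_total) {
  const NumericMatrix phi = ebasis["phi"], dphi = ebasis["dphi"];
  const NumericVector wq = ebasis["w"];
  const int nen = phi.nrow(), nq = phi.ncol(), ne = edges.ncol();
  NumericVector F(ndof_total);
  double fz = 0.0, fr = 0.0;
  const double TWO_PI = 2.0 * M_PI;
  for (int e = 0; e < ne; ++e) {
    for (int q = 0; q < nq; ++q) {
      double r = 0, dr = 0, dz = 0;
      for (int n = 0; n < nen; ++n) {
        const int g = edges(n, e) - 1;
        const double xr = nodes(g, 0) + u[2 * g];
        const double xz = nodes(g, 1) + u[2 * g + 1];
        r += phi(n, q) * xr;
        dr += dphi(n, q) * xr;
        dz += dphi(n, q) * xz;
      }
      const double wgt = wq[q] * TWO_PI * r * (-p);
      // n |J| = (dz, -dr)
      for (int n = 0; n < nen; ++n) {
        const int g = edges(n, e) - 1;
        F[2 * g] += wgt * phi(n, q) * dz;
        F[2 * g + 1] += wgt * phi(n, q) * (-dr);
      }
      fr += wgt * dz;
      fz += wgt * (-dr);
    }
  }
  return List::create(_["F"] = F, _["fz"] = fz, _["fr"] = fr);
}

// Node-to-segment penalty contact against a curved master surface,
// frictionless (mode 0) or tied (mode 1). The master is given as higher-order
// boundary edges; each edge is sampled at `sub_phi` (nen_e x (nsub+1) basis
// values) into nsub straight sub-segments, keeping the chordal gap error far
// below the physical penetrations of interest. Master edges are ordered with
// the master body (eye) on the LEFT, so the outward normal (t_z, -t_r)/|t|
// points into the slave (fat) side and gap > 0 means separation. Forces act
// along the surface normal only (no tangential transfer).
//' @noRd
// [[Rcpp::export(name = "asm_contact_cpp")]]
List asm_contact_cpp(NumericMatrix nodes, NumericVector u,
                     IntegerVector slave, NumericVector slave_w,
                     IntegerMatrix master_edges, NumericMatrix sub_phi,
                     NumericMatrix basisC,
                     double kp, double g0, IntegerVector smode,
                     IntegerVector tied_edge, NumericVector tied_s) {
  const int ns = slave.size();
  const int nen = master_edges.nrow(), ne = master_edges.ncol();
  const int nsub = sub_phi.ncol() - 1;
  const int nseg = ne * nsub;
  const int N = nodes.nrow();
  NumericVector F(2 * N);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  NumericVector gap(ns), pn(ns);
  IntegerVector segout(ns);
  NumericVector tout(ns);
  double fz_master = 0.0, energy = 0.0;
  // sampled polyline: per edge, nsub+1 points
  std::vector<double> px((nsub + 1) * ne), pz((nsub + 1) * ne);
  for (int e = 0; e < ne; ++e) {
    for (int k = 0; k <= nsub; ++k) {
      double xr = 0, xz = 0;
      for (int i = 0; i < nen; ++i) {
        const int g = master_edges(i, e) - 1;
        xr += sub_phi(i, k) * (nodes(g, 0) + u[2 * g]);
        xz += sub_phi(i, k) * (nodes(g, 1) + u[2 * g + 1]);
      }
      px[e * (nsub + 1) + k] = xr;
      pz[e * (nsub + 1) + k] = xz;
    }
  }
  std::vector<double> cw(nen);
  for (int s = 0; s < ns; ++s) {
    const int gs = slave[s] - 1;
    const double xs = nodes(gs, 0) + u[2 * gs];
    const double zs = nodes(gs, 1) + u[2 * gs + 1];
    int best = -1;
    double bt = 0, bd2 = 1e300;
    if (smode[s] == 1 && tied_edge[s] > 0) {
      // tied slave: fixed material pairing (edge, parameter)
      const int e = tied_edge[s] - 1;
      const double sloc = tied_s[s];
      std::vector<double> phs(nen);
      double qx = 0, qz = 0;
      for (int i = 0; i < nen; ++i) {
        const int g2 = master_edges(i, e) - 1;
        double ph = 0;
        for (int j2 = 0; j2 < nen; ++j2) ph += basisC(j2, i) * std::pow(sloc, j2);
        phs[i] = ph;
        qx += ph * (nodes(g2, 0) + u[2 * g2]);
        qz += ph * (nodes(g2, 1) + u[2 * g2 + 1]);
      }
      const double dx = xs - qx, dz2 = zs - qz;
      const double w = slave_w[s] * 2.0 * M_PI * std::max(xs, 1e-9);
      const double fxs = -kp * w * dx, fzs = -kp * w * dz2;
      F[2 * gs] += fxs; F[2 * gs + 1] += fzs;
      for (int i = 0; i < nen; ++i) {
        const int gm = master_edges(i, e) - 1;
        F[2 * gm] -= phs[i] * fxs;
        F[2 * gm + 1] -= phs[i] * fzs;
      }
      fz_master -= fzs;
      energy += 0.5 * kp * w * (dx * dx + dz2 * dz2);
      gap[s] = 0;
      pn[s] = kp * std::sqrt(dx * dx + dz2 * dz2);
      segout[s] = e + 1;
      tout[s] = sloc;
      std::vector<int> dofs(1 + nen);
      std::vector<double> cf(1 + nen);
      dofs[0] = gs; cf[0] = 1.0;
      for (int i = 0; i < nen; ++i) {
        dofs[1 + i] = master_edges(i, e) - 1;
        cf[1 + i] = -phs[i];
      }
      for (size_t a2 = 0; a2 < dofs.size(); ++a2)
        for (size_t b2 = 0; b2 < dofs.size(); ++b2)
          for (int d = 0; d < 2; ++d) {
            const double v = kp * w * cf[a2] * cf[b2];
            ti.push_back(2 * dofs[a2] + d + 1);
            tj.push_back(2 * dofs[b2] + d + 1);
            tx.push_back(v);
          }
      continue;
    }
    {
      for (int q = 0; q < nseg; ++q) {
        const int e = q / nsub, k = q % nsub;
        const double ax = px[e * (nsub + 1) + k], az = pz[e * (nsub + 1) + k];
        const double ex = px[e * (nsub + 1) + k + 1] - ax;
        const double ez = pz[e * (nsub + 1) + k + 1] - az;
        const double L2 = ex * ex + ez * ez;
        if (L2 <= 0) continue;
        double t = ((xs - ax) * ex + (zs - az) * ez) / L2;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        const double qx = ax + t * ex, qz = az + t * ez;
        const double d2 = (xs - qx) * (xs - qx) + (zs - qz) * (zs - qz);
        if (d2 < bd2) { bd2 = d2; best = q; bt = t; }
      }
    }
    segout[s] = best + 1;
    tout[s] = bt;
    if (best < 0) { gap[s] = NA_REAL; continue; }
    // refine: smooth closest-point projection onto the quadratic edges
    // themselves (continuous normals along an edge; Newton on the edge
    // parameter). Near edge junctions the true foot may sit on a neighbour,
    // so the facet edge and both neighbours are tried.
    const int e0 = best / nsub;
    int ebest = -1;
    double sbest = 0, dbest = 1e300;
    std::vector<double> exr(nen), exz(nen);
    for (int ecand = std::max(0, e0 - 1); ecand <= std::min(ne - 1, e0 + 1); ++ecand) {
      for (int i = 0; i < nen; ++i) {
        const int g2 = master_edges(i, ecand) - 1;
        exr[i] = nodes(g2, 0) + u[2 * g2];
        exz[i] = nodes(g2, 1) + u[2 * g2 + 1];
      }
      double sloc = (ecand == e0) ? (best % nsub + bt) / nsub : 0.5;
      for (int ni = 0; ni < 8; ++ni) {
        double qx_ = 0, qz_ = 0, dx_ = 0, dz_ = 0, hx_ = 0, hz_ = 0;
        for (int i = 0; i < nen; ++i) {
          double ph = 0, dph = 0, ddph = 0;
          for (int j2 = 0; j2 < nen; ++j2) {
            const double c = basisC(j2, i);
            ph += c * std::pow(sloc, j2);
            if (j2 >= 1) dph += c * j2 * std::pow(sloc, j2 - 1);
            if (j2 >= 2) ddph += c * j2 * (j2 - 1) * std::pow(sloc, j2 - 2);
          }
          qx_ += ph * exr[i]; qz_ += ph * exz[i];
          dx_ += dph * exr[i]; dz_ += dph * exz[i];
          hx_ += ddph * exr[i]; hz_ += ddph * exz[i];
        }
        const double f1 = (xs - qx_) * dx_ + (zs - qz_) * dz_;
        const double f2 = -(dx_ * dx_ + dz_ * dz_) + (xs - qx_) * hx_ + (zs - qz_) * hz_;
        if (!std::isfinite(f2) || std::fabs(f2) < 1e-30) break;
        double snew = sloc - f1 / f2;
        if (!std::isfinite(snew)) break;
        if (snew < 0) snew = 0;
        if (snew > 1) snew = 1;
        if (std::fabs(snew - sloc) < 1e-12) { sloc = snew; break; }
        sloc = snew;
      }
      double qx_ = 0, qz_ = 0;
      for (int i = 0; i < nen; ++i) {
        double ph = 0;
        for (int j2 = 0; j2 < nen; ++j2) ph += basisC(j2, i) * std::pow(sloc, j2);
        qx_ += ph * exr[i]; qz_ += ph * exz[i];
      }
      const double d2c = (xs - qx_) * (xs - qx_) + (zs - qz_) * (zs - qz_);
      if (d2c < dbest) { dbest = d2c; ebest = ecand; sbest = sloc; }
    }
    const int e = ebest;
    double sloc = sbest;
    // the physical surface continues below the posterior end (the nerve runs
    // on into the optic canal): project onto the tangent ray at the end
    bool end_ray = (e == 0 && sloc <= 1e-9);
    if (end_ray) sloc = 0.0;
    for (int i = 0; i < nen; ++i) {
      const int g2 = master_edges(i, e) - 1;
      exr[i] = nodes(g2, 0) + u[2 * g2];
      exz[i] = nodes(g2, 1) + u[2 * g2 + 1];
    }
    std::vector<double> phs(nen);
    double qx = 0, qz = 0, tx2 = 0, tz2 = 0;
    for (int i = 0; i < nen; ++i) {
      double ph = 0, dph = 0;
      for (int j2 = 0; j2 < nen; ++j2) {
        const double c = basisC(j2, i);
        ph += c * std::pow(sloc, j2);
        if (j2 >= 1) dph += c * j2 * std::pow(sloc, j2 - 1);
      }
      phs[i] = ph;
      qx += ph * exr[i]; qz += ph * exz[i];
      tx2 += dph * exr[i]; tz2 += dph * exz[i];
    }
    const double Ls = std::sqrt(tx2 * tx2 + tz2 * tz2);
    const double nx = tz2 / Ls, nz = -tx2 / Ls; // outward from master body
    double dx = xs - qx, dz2 = zs - qz;
    if (end_ray) {
      // gap measured against the tangent ray through the end point
      const double tpar = (dx * tx2 + dz2 * tz2) / Ls;
      (void)tpar;
      dx = xs - qx; dz2 = zs - qz;
    }
    const double g = dx * nx + dz2 * nz;
    gap[s] = g;
    tout[s] = sloc;
    segout[s] = e + 1; // parent edge of the smooth projection
    const double w = slave_w[s] * 2.0 * M_PI * std::max(xs, 1e-9);
    // contact-point interpolation weights on the parent edge nodes
    for (int i = 0; i < nen; ++i) cw[i] = phs[i];
    // C1-smoothed penalty: quadratic transition of half-width g0 around
    // grazing contact removes the activation kink that stalls Newton.
    double pres, dpdg;
    if (g >= g0) {
      pn[s] = 0;
      continue;
    } else if (g > -g0) {
      pres = kp * (g - g0) * (g - g0) / (4.0 * g0);
      dpdg = kp * (g - g0) / (2.0 * g0);
    } else {
      pres = -kp * g;
      dpdg = -kp;
    }
    pn[s] = pres;
    const double fs = pres * w; // uN on the slave ring, along +n
    F[2 * gs] += fs * nx;
    F[2 * gs + 1] += fs * nz;
    for (int i = 0; i < nen; ++i) {
      const int gm = master_edges(i, e) - 1;
      F[2 * gm] -= cw[i] * fs * nx;
      F[2 * gm + 1] -= cw[i] * fs * nz;
    }
    fz_master -= fs * nz;
    energy += 0.5 * w * pres * std::max(g0 - g, 0.0); // ~ stored penalty energy
    // K = (-dp/dg) w (grad g)(grad g)^T; grad g: +n on slave, -cw_i n masters
    const double keff = -dpdg;
    const double nv[2] = {nx, nz};
    std::vector<int> dofs(1 + nen);
    std::vector<double> cf(1 + nen);
    dofs[0] = gs; cf[0] = 1.0;
    for (int i = 0; i < nen; ++i) {
      dofs[1 + i] = master_edges(i, e) - 1;
      cf[1 + i] = -cw[i];
    }
    for (size_t a2 = 0; a2 < dofs.size(); ++a2)
      for (size_t b2 = 0; b2 < dofs.size(); ++b2)
        for (int d1 = 0; d1 < 2; ++d1)
          for (int d2 = 0; d2 < 2; ++d2) {
            const double v = keff * w * cf[a2] * cf[b2] * nv[d1] * nv[d2];
            if (v != 0.0) {
              ti.push_back(2 * dofs[a2] + d1 + 1);
              tj.push_back(2 * dofs[b2] + d2 + 1);
              tx.push_back(v);
            }
          }
  }
  return List::create(_["F"] = F,
                      _["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()),
                      _["gap"] = gap, _["pn"] = pn, _["seg"] = segout,
                      _["t"] = tout, _["fz_master"] = fz_master,
                      _["energy"] = energy);
}
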