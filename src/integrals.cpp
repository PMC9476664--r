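// Gaussian integral engine: McMurchie-Davidson scheme over contracted
// Cartesian shells.  Supports the ordinary Coulomb kernel 1/r12 and the
// erf-attenuated kernel erf(w r12)/r12 (w > 0) used by the attenuated-metric
// density fitting.  Angular momentum is general; Cartesian components are
// ordered lexicographically with lx descending, then ly descending.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

struct Shell {
  int l;
  double cx, cy, cz;
  std::vector<double> exps;
  // coef[prim][comp]: contraction coefficients with primitive and contracted
  // normalisation folded in (per Cartesian component)
  std::vector< std::vector<double> > coef;
  int ncomp() const { return (l + 1) * (l + 2) / 2; }
};

static double odd_dfact(int l) { // (2l-1)!!, l >= 0
  double r = 1.0;
  for (int k = 2 * l - 1; k > 1; k -= 2) r *= k;
  return r;
}

static void comp_list(int l, std::vector<int>& lx, std::vector<int>& ly,
                      std::vector<int>& lz) {
  lx.clear(); ly.clear(); lz.clear();
  for (int ax = l; ax >= 0; --ax)
    for (int ay = l - ax; ay >= 0; --ay) {
      lx.push_back(ax); ly.push_back(ay); lz.push_back(l - ax - ay);
    }
}

static double prim_norm(double a, int ax, int ay, int az) {
  int l = ax + ay + az;
  return std::pow(2.0 * a / PI, 0.75) * std::pow(4.0 * a, 0.5 * l) /
         std::sqrt(odd_dfact(ax) * odd_dfact(ay) * odd_dfact(az));
}

// Parse shells from R list-of-lists: each list(l=, center=, exps=, coefs=).
static std::vector<Shell> parse_shells(const List& shells) {
  int ns = shells.size();
  std::vector<Shell> out(ns);
  for (int s = 0; s < ns; ++s) {
    List sh = shells[s];
    Shell& S = out[s];
    S.l = as<int>(sh["l"]);
    NumericVector c = sh["center"];
    S.cx = c[0]; S.cy = c[1]; S.cz = c[2];
    NumericVector e = sh["exps"], k = sh["coefs"];
    int np = e.size();
    S.exps.assign(e.begin(), e.end());
    std::vector<int> ax, ay, az;
    comp_list(S.l, ax, ay, az);
    int nc = S.ncomp();
    S.coef.assign(np, std::vector<double>(nc));
    for (int p = 0; p < np; ++p)
      for (int m = 0; m < nc; ++m)
        S.coef[p][m] = k[p] * prim_norm(S.exps[p], ax[m], ay[m], az[m]);
    // contracted normalisation per component (same-centre analytic overlap)
    for (int m = 0; m < nc; ++m) {
      double ss = 0.0;
      for (int p = 0; p < np; ++p)
        for (int q = 0; q < np; ++q) {
          double pp = S.exps[p] + S.exps[q];
          double s1 = std::pow(PI / pp, 1.5) *
            odd_dfact(ax[m]) * odd_dfact(ay[m]) * odd_dfact(az[m]) /
            std::pow(2.0 * pp, S.l);
          ss += S.coef[p][m] * S.coef[q][m] * s1;
        }
      double nrm = 1.0 / std::sqrt(ss);
      for (int p = 0; p < np; ++p) S.coef[p][m] *= nrm;
    }
  }
  return out;
}

// Boys function F_0..F_n at T (series/downward for small T, upward for large)
static void boys(int n, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= n; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(PI / T);
    double eT = (T < 700.0) ? std::exp(-T) : 0.0;
    for (int m = 0; m < n; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
    return;
  }
  // series for F_n, then downward
  double eT = std::exp(-T);
  double term = 1.0 / (2.0 * n + 1.0), sum = term;
  for (int i = 1; i < 200; ++i) {
    term *= 2.0 * T / (2.0 * n + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[n] = eT * sum;
  for (int m = n - 1; m >= 0; --m)
    F[m] = (2.0 * T * F[m + 1] + eT) / (2.0 * m + 1.0);
}

// Hermite expansion coefficients E[i][j][t] for one Cartesian direction
struct Etab {
  int imax, jmax;
  std::vector<double> v; // (imax+1)*(jmax+1)*(imax+jmax+1)
  double at(int i, int j, int t) const {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
  double& at(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

static Etab hermite_E(int imax, int jmax, double a, double b, double A,
                      double B) {
  Etab E;
  E.imax = imax; E.jmax = jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (imax + jmax + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double AB = A - B, P = (a * A + b * B) / p;
  double PA = P - A, PB = P - B;
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          if (t > 0) val += E.at(i - 1, j, t - 1) / (2.0 * p);
          if (t <= i - 1 + j) val += PA * E.at(i - 1, j, t);
          if (t + 1 <= i - 1 + j) val += (t + 1.0) * E.at(i - 1, j, t + 1);
        } else {
          if (t > 0) val += E.at(i, j - 1, t - 1) / (2.0 * p);
          if (t <= i + j - 1) val += PB * E.at(i, j - 1, t);
          if (t + 1 <= i + j - 1) val += (t + 1.0) * E.at(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  return E;
}

// Hermite Coulomb repulsion tensor R^0_{tuv} for t+u+v <= L.
// alpha: effective exponent; (X,Y,Z): separation; att in (0,1]: kernel
// attenuation factor w^2/(w^2+alpha) (1 for plain Coulomb).
struct Rtab {
  int L;
  std::vector<double> v; // indexed [t][u][v]
  double at(int t, int u, int vv) const {
    return v[(t * (L + 1) + u) * (L + 1) + vv];
  }
};

static Rtab hermite_R(int L, double alpha, double X, double Y, double Z,
                      double att) {
  double T = alpha * (X * X + Y * Y + Z * Z) * att;
  std::vector<double> F(L + 1);
  boys(L, T, F.data());
  double katt = std::sqrt(att);
  // F_n -> att^{n+1/2} F_n(att*T)
  for (int n = 0; n <= L; ++n) F[n] *= katt * std::pow(att, n);
  // Rn[n][t][u][v]
  int d = L + 1;
  std::vector<double> Rn((L + 1) * d * d * d, 0.0);
  auto idx = [d](int n, int t, int u, int v) {
    return ((n * d + t) * d + u) * d + v;
  };
  for (int n = 0; n <= L; ++n)
    Rn[idx(n, 0, 0, 0)] = std::pow(-2.0 * alpha, n) * F[n];
  for (int sum = 1; sum <= L; ++sum)
    for (int t = 0; t <= sum; ++t)
      for (int u = 0; u <= sum - t; ++u) {
        int v = sum - t - u;
        for (int n = 0; n <= L - sum; ++n) {
          double val = 0.0;
          if (t > 0) {
            if (t > 1) val += (t - 1.0) * Rn[idx(n + 1, t - 2, u, v)];
            val += X * Rn[idx(n + 1, t - 1, u, v)];
          } else if (u > 0) {
            if (u > 1) val += (u - 1.0) * Rn[idx(n + 1, t, u - 2, v)];
            val += Y * Rn[idx(n + 1, t, u - 1, v)];
          } else {
            if (v > 1) val += (v - 1.0) * Rn[idx(n + 1, t, u, v - 2)];
            val += Z * Rn[idx(n + 1, t, u, v - 1)];
          }
          Rn[idx(n, t, u, v)] = val;
        }
      }
  Rtab R;
  R.L = L;
  R.v.assign(d * d * d, 0.0);
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int v = 0; v <= L - t - u; ++v)
        R.v[(t * d + u) * d + v] = Rn[idx(0, t, u, v)];
  return R;
}

static int n_basis(const std::vector<Shell>& sh) {
  int n = 0;
  for (size_t s = 0; s < sh.size(); ++s) n += sh[s].ncomp();
  return n;
}

// [[Rcpp::export]]
List cpp_one_electron(List shells, NumericMatrix atom_coords,
                      NumericVector atom_charges) {
  std::vector<Shell> sh = parse_shells(shells);
  int nb = n_basis(sh), ns = sh.size();
  NumericMatrix S(nb, nb), T(nb, nb), V(nb, nb);
  std::vector<int> off(ns, 0);
  for (int s = 1; s < ns; ++s) off[s] = off[s - 1] + sh[s - 1].ncomp();
  for (int s1 = 0; s1 < ns; ++s1)
    for (int s2 = s1; s2 < ns; ++s2) {
      const Shell &A = sh[s1], &B = sh[s2];
      std::vector<int> ax, ay, az, bx, by, bz;
      comp_list(A.l, ax, ay, az);
      comp_list(B.l, bx, by, bz);
      int na = A.ncomp(), nbc = B.ncomp();
      std::vector<double> Sblk(na * nbc, 0.0), Tblk(na * nbc, 0.0),
          Vblk(na * nbc, 0.0);
      for (size_t p = 0; p < A.exps.size(); ++p)
        for (size_t q = 0; q < B.exps.size(); ++q) {
          double a = A.exps[p], b = B.exps[q], pp = a + b;
          // E tables up to l+2 in bra for kinetic via ket raise
          Etab Ex = hermite_E(A.l, B.l + 2, a, b, A.cx, B.cx);
          Etab Ey = hermite_E(A.l, B.l + 2, a, b, A.cy, B.cy);
          Etab Ez = hermite_E(A.l, B.l + 2, a, b, A.cz, B.cz);
          double sfac = std::pow(PI / pp, 1.5);
          double Px = (a * A.cx + b * B.cx) / pp;
          double Py = (a * A.cy + b * B.cy) / pp;
          double Pz = (a * A.cz + b * B.cz) / pp;
          int Lsum = A.l + B.l;
          // nuclear attraction hermite charge distributions
          std::vector<Rtab> Rnuc;
          for (int at = 0; at < atom_coords.nrow(); ++at)
            Rnuc.push_back(hermite_R(Lsum, pp, Px - atom_coords(at, 0),
                                     Py - atom_coords(at, 1),
                                     Pz - atom_coords(at, 2), 1.0));
          for (int i = 0; i < na; ++i)
            for (int j = 0; j < nbc; ++j) {
              double cc = A.coef[p][i] * B.coef[q][j];
              double sx = Ex.at(ax[i], bx[j], 0);
              double sy = Ey.at(ay[i], by[j], 0);
              double sz = Ez.at(az[i], bz[j], 0);
              Sblk[i * nbc + j] += cc * sfac * sx * sy * sz;
              // kinetic: T = -1/2 sum_d d2/dx2 acting on ket
              auto t1d = [&](const Etab& E, int ia, int jb) {
                double tjj = -2.0 * b * b * E.at(ia, jb + 2, 0) +
                             b * (2.0 * jb + 1.0) * E.at(ia, jb, 0);
                if (jb >= 2)
                  tjj -= 0.5 * jb * (jb - 1.0) * E.at(ia, jb - 2, 0);
                return tjj;
              };
              double tx = t1d(Ex, ax[i], bx[j]);
              double ty = t1d(Ey, ay[i], by[j]);
              double tz = t1d(Ez, az[i], bz[j]);
              Tblk[i * nbc + j] +=
                  cc * sfac * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
              // nuclear attraction
              double vsum = 0.0;
              for (int at = 0; at < atom_coords.nrow(); ++at) {
                double vat = 0.0;
                for (int t = 0; t <= ax[i] + bx[j]; ++t)
                  for (int u = 0; u <= ay[i] + by[j]; ++u)
                    for (int v = 0; v <= az[i] + bz[j]; ++v)
                      vat += Ex.at(ax[i], bx[j], t) * Ey.at(ay[i], by[j], u) *
                             Ez.at(az[i], bz[j], v) * Rnuc[at].at(t, u, v);
                vsum -= atom_charges[at] * vat;
              }
              Vblk[i * nbc + j] += cc * (2.0 * PI / pp) * vsum;
            }
        }
      for (int i = 0; i < na; ++i)
        for (int j = 0; j < nbc; ++j) {
          int I = off[s1] + i, J = off[s2] + j;
          S(I, J) = S(J, I) = Sblk[i * nbc + j];
          T(I, J) = T(J, I) = Tblk[i * nbc + j];
          V(I, J) = V(J, I) = Vblk[i * nbc + j];
        }
    }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// Generic contracted ERI over four shells; returns block [na*nb*nc*nd]
static void eri_shell_quartet(const Shell& A, const Shell& B, const Shell& C,
                              const Shell& D, double omega,
                              std::vector<double>& out) {
  std::vector<int> ax, ay, az, bx, by, bz, cx_, cy_, cz_, dx, dy, dz;
  comp_list(A.l, ax, ay, az);
  comp_list(B.l, bx, by, bz);
  comp_list(C.l, cx_, cy_, cz_);
  comp_list(D.l, dx, dy, dz);
  int na = A.ncomp(), nb = B.ncomp(), nc = C.ncomp(), nd = D.ncomp();
  out.assign(na * nb * nc * nd, 0.0);
  int L = A.l + B.l + C.l + D.l;
  for (size_t p1 = 0; p1 < A.exps.size(); ++p1)
    for (size_t p2 = 0; p2 < B.exps.size(); ++p2) {
      double a = A.exps[p1], b = B.exps[p2], pp = a + b;
      Etab E1x = hermite_E(A.l, B.l, a, b, A.cx, B.cx);
      Etab E1y = hermite_E(A.l, B.l, a, b, A.cy, B.cy);
      Etab E1z = hermite_E(A.l, B.l, a, b, A.cz, B.cz);
      double Px = (a * A.cx + b * B.cx) / pp;
      double Py = (a * A.cy + b * B.cy) / pp;
      double Pz = (a * A.cz + b * B.cz) / pp;
      for (size_t p3 = 0; p3 < C.exps.size(); ++p3)
        for (size_t p4 = 0; p4 < D.exps.size(); ++p4) {
          double c = C.exps[p3], d = D.exps[p4], qq = c + d;
          Etab E2x = hermite_E(C.l, D.l, c, d, C.cx, D.cx);
          Etab E2y = hermite_E(C.l, D.l, c, d, C.cy, D.cy);
          Etab E2z = hermite_E(C.l, D.l, c, d, C.cz, D.cz);
          double Qx = (c * C.cx + d * D.cx) / qq;
          double Qy = (c * C.cy + d * D.cy) / qq;
          double Qz = (c * C.cz + d * D.cz) / qq;
          double rho = pp * qq / (pp + qq);
          double att = (omega > 0.0)
                           ? omega * omega / (omega * omega + rho)
                           : 1.0;
          Rtab R = hermite_R(L, rho, Px - Qx, Py - Qy, Pz - Qz, att);
          double pref =
              2.0 * std::pow(PI, 2.5) / (pp * qq * std::sqrt(pp + qq));
          for (int i = 0; i < na; ++i)
            for (int j = 0; j < nb; ++j) {
              double cc1 = A.coef[p1][i] * B.coef[p2][j];
              if (cc1 == 0.0) continue;
              for (int k = 0; k < nc; ++k)
                for (int l = 0; l < nd; ++l) {
                  double cc = cc1 * C.coef[p3][k] * D.coef[p4][l];
                  double val = 0.0;
                  for (int t = 0; t <= ax[i] + bx[j]; ++t)
                    for (int u = 0; u <= ay[i] + by[j]; ++u)
                      for (int v = 0; v <= az[i] + bz[j]; ++v) {
                        double e1 = E1x.at(ax[i], bx[j], t) *
                                    E1y.at(ay[i], by[j], u) *
                                    E1z.at(az[i], bz[j], v);
                        if (e1 == 0.0) continue;
                        double acc = 0.0;
                        for (int tt = 0; tt <= cx_[k] + dx[l]; ++tt)
                          for (int uu = 0; uu <= cy_[k] + dy[l]; ++uu)
                            for (int vv = 0; vv <= cz_[k] + dz[l]; ++vv) {
                              double e2 = E2x.at(cx_[k], dx[l], tt) *
                                          E2y.at(cy_[k], dy[l], uu) *
                                          E2z.at(cz_[k], dz[l], vv);
                              if (e2 == 0.0) continue;
                              double sgn =
                                  ((tt + uu + vv) % 2 == 0) ? 1.0 : -1.0;
                              acc += sgn * e2 * R.at(t + tt, u + uu, v + vv);
                            }
                        val += e1 * acc;
                      }
                  out[((i * nb + j) * nc + k) * nd + l] += cc * pref * val;
                }
            }
        }
    }
}

// [[Rcpp::export]]
NumericVector cpp_eri_dense(List shells, double omega) {
  std::vector<Shell> sh = parse_shells(shells);
  int nb = n_basis(sh), ns = sh.size();
  NumericVector out((size_t)nb * nb * nb * nb);
  out.attr("dim") = IntegerVector::create(nb, nb, nb, nb);
  std::vector<int> off(ns, 0);
  for (int s = 1; s < ns; ++s) off[s] = off[s - 1] + sh[s - 1].ncomp();
  std::vector<double> blk;
  double* o = out.begin();
  size_t n1 = nb, n2 = (size_t)nb * nb, n3 = (size_t)nb * nb * nb;
  for (int s1 = 0; s1 < ns; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2)
      for (int s3 = 0; s3 <= s1; ++s3)
        for (int s4 = 0; s4 <= (s3 == s1 ? s2 : s3); ++s4) {
          eri_shell_quartet(sh[s1], sh[s2], sh[s3], sh[s4], omega, blk);
          int na = sh[s1].ncomp(), nbb = sh[s2].ncomp(), ncc = sh[s3].ncomp(),
              ndd = sh[s4].ncomp();
          for (int i = 0; i < na; ++i)
            for (int j = 0; j < nbb; ++j)
              for (int k = 0; k < ncc; ++k)
                for (int l = 0; l < ndd; ++l) {
                  double v = blk[((i * nbb + j) * ncc + k) * ndd + l];
                  size_t I = off[s1] + i, J = off[s2] + j, K = off[s3] + k,
                         Lx = off[s4] + l;
                  o[I + J * n1 + K * n2 + Lx * n3] = v;
                  o[J + I * n1 + K * n2 + Lx * n3] = v;
                  o[I + J * n1 + Lx * n2 + K * n3] = v;
                  o[J + I * n1 + Lx * n2 + K * n3] = v;
                  o[K + Lx * n1 + I * n2 + J * n3] = v;
                  o[Lx + K * n1 + I * n2 + J * n3] = v;
                  o[K + Lx * n1 + J * n2 + I * n3] = v;
                  o[Lx + K * n1 + J * n2 + I * n3] = v;
                }
        }
  return out;
}

// Three-centre (mu nu | alpha) integrals: returns array nb x nb x naux
// [[Rcpp::export]]
NumericVector cpp_eri_3c(List shells, List aux_shells, double omega) {
  std::vector<Shell> sh = parse_shells(shells);
  std::vector<Shell> ax = parse_shells(aux_shells);
  int nb = n_basis(sh), na = n_basis(ax);
  int ns = sh.size(), nsa = ax.size();
  NumericVector out(Dimension(nb, nb, na));
  std::vector<int> off(ns, 0), offa(nsa, 0);
  for (int s = 1; s < ns; ++s) off[s] = off[s - 1] + sh[s - 1].ncomp();
  for (int s = 1; s < nsa; ++s) offa[s] = offa[s - 1] + ax[s - 1].ncomp();
  // unit s "shell" to reuse 4-centre code
  Shell unit;
  unit.l = 0; unit.cx = unit.cy = unit.cz = 0.0;
  unit.exps.assign(1, 0.0);
  unit.coef.assign(1, std::vector<double>(1, 1.0));
  std::vector<double> blk;
  double* o = out.begin();
  size_t n1 = nb, n2 = (size_t)nb * nb;
  for (int s1 = 0; s1 < ns; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2)
      for (int s3 = 0; s3 < nsa; ++s3) {
        // aux charge distribution: single shell x unit dummy with zero
        // exponent and coefficient 1 (plain Gaussian product works since the
        // dummy contributes exp(0)=1 and no angular factor)
        Shell dummy = unit;
        dummy.cx = ax[s3].cx; dummy.cy = ax[s3].cy; dummy.cz = ax[s3].cz;
        eri_shell_quartet(sh[s1], sh[s2], ax[s3], dummy, omega, blk);
        int nA = sh[s1].ncomp(), nB = sh[s2].ncomp(), nC = ax[s3].ncomp();
        for (int i = 0; i < nA; ++i)
          for (int j = 0; j < nB; ++j)
            for (int k = 0; k < nC; ++k) {
              double v = blk[(i * nB + j) * nC + k];
              size_t I = off[s1] + i, J = off[s2] + j, K = offa[s3] + k;
              o[I + J * n1 + K * n2] = v;
              o[J + I * n1 + K * n2] = v;
            }
      }
  return out;
}

// Two-centre (alpha | beta) metric integrals
// [[Rcpp::export]]
NumericMatrix cpp_eri_2c(List aux_shells, double omega) {
  std::vector<Shell> ax = parse_shells(aux_shells);
  int na = n_basis(ax), nsa = ax.size();
  NumericMatrix out(na, na);
  std::vector<int> offa(nsa, 0);
  for (int s = 1; s < nsa; ++s) offa[s] = offa[s - 1] + ax[s - 1].ncomp();
  Shell unit;
  unit.l = 0;
  unit.exps.assign(1, 0.0);
  unit.coef.assign(1, std::vector<double>(1, 1.0));
  std::vector<double> blk;
  for (int s1 = 0; s1 < nsa; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      Shell d1 = unit, d2 = unit;
      d1.cx = ax[s1].cx; d1.cy = ax[s1].cy; d1.cz = ax[s1].cz;
      d2.cx = ax[s2].cx; d2.cy = ax[s2].cy; d2.cz = ax[s2].cz;
      eri_shell_quartet(ax[s1], d1, ax[s2], d2, omega, blk);
      int nA = ax[s1].ncomp(), nB = ax[s2].ncomp();
      for (int i = 0; i < nA; ++i)
        for (int k = 0; k < nB; ++k) {
          double v = blk[(i * 1 + 0) * nB * 1 + k * 1];
          out(offa[s1] + i, offa[s2] + k) = v;
          out(offa[s2] + k, offa[s1] + i) = v;
        }
    }
  return out;
}

// Basis-function values at points: returns nb x npts matrix
// [[Rcpp::export]]
NumericMatrix cpp_collocate(List shells, NumericMatrix pts) {
  std::vector<Shell> sh = parse_shells(shells);
  int nb = n_basis(sh), np = pts.nrow(), ns = sh.size();
  NumericMatrix out(nb, np);
  std::vector<int> off(ns, 0);
  for (int s = 1; s < ns; ++s) off[s] = off[s - 1] + sh[s - 1].ncomp();
  for (int s = 0; s < ns; ++s) {
    const Shell& S = sh[s];
    std::vector<int> ax, ay, az;
    comp_list(S.l, ax, ay, az);
    int nc = S.ncomp();
    for (int P = 0; P < np; ++P) {
      double dx = pts(P, 0) - S.cx, dy = pts(P, 1) - S.cy,
             dz = pts(P, 2) - S.cz;
      double r2 = dx * dx + dy * dy + dz * dz;
      for (int m = 0; m < nc; ++m) {
        double ang = std::pow(dx, ax[m]) * std::pow(dy, ay[m]) *
                     std::pow(dz, az[m]);
        double val = 0.0;
        for (size_t p = 0; p < S.exps.size(); ++p) {
          double ex = S.exps[p] * r2;
          if (ex < 700.0) val += S.coef[p][m] * std::exp(-ex);
        }
        out(off[s] + m, P) = val * ang;
      }
    }
  }
  return out;
}
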