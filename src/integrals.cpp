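// Gaussian integral primitives: McMurchie-Davidson recursions over Hermite
// Gaussians with pluggable radial kernels.  Supported two-electron kernels:
// Coulomb 1/r12, Gaussian geminal exp(-beta r12^2), and Gaussian-damped
// Coulomb exp(-beta r12^2)/r12; the same three kinds double as grid-point
// one-electron kernels (point attraction, three-center overlap, damped point
// attraction).  Angular momenta up to d (l = 2) are supported; higher shells
// are rejected in the R layer.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int LMAX = 2;        // d functions
static const int EMAX = 2 * LMAX + 2;  // 1D Hermite order cap (kinetic needs l+2)
static const int NMAX = 4 * LMAX;      // total Hermite order of a 4c2e quartet

// ---------------------------------------------------------------------------
// Boys function F_m(x), m = 0..mmax, absolute accuracy ~1e-14 on [0, inf).
// Ascending series (all-positive, stable) for x <= 40 evaluated at m = mmax
// followed by downward recursion; large-x asymptotics with upward recursion
// otherwise (the exp(-x) correction is below 4e-18 there).
static void boys_row(int mmax, double x, double* F) {
  if (x <= 40.0) {
    double term = 1.0 / (2.0 * mmax + 1.0);
    double sum = term;
    for (int k = 1; k < 300; ++k) {
      term *= 2.0 * x / (2.0 * mmax + 2.0 * k + 1.0);
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    double ex = std::exp(-x);
    F[mmax] = ex * sum;
    for (int m = mmax; m > 0; --m)
      F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(M_PI / x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = (2.0 * m + 1.0) * F[m] / (2.0 * x);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_boys(int mmax, NumericVector x) {
  NumericMatrix out(x.size(), mmax + 1);
  std::vector<double> row(mmax + 1);
  for (int i = 0; i < x.size(); ++i) {
    boys_row(mmax, x[i], row.data());
    for (int m = 0; m <= mmax; ++m) out(i, m) = row[m];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Shell containers

struct ShellSet {
  std::vector<int> l, ps, pn, ao_off, ncomp;
  std::vector<double> cx, cy, cz, pe, pc;
  int nsh, nao;
};

static ShellSet parse_shells(List s) {
  ShellSet S;
  IntegerVector l = s["l"], ps = s["pstart"], pn = s["pnum"];
  NumericVector cx = s["cx"], cy = s["cy"], cz = s["cz"];
  NumericVector pe = s["pexp"], pc = s["pcoef"];
  S.nsh = l.size();
  S.l.assign(l.begin(), l.end());
  S.ps.assign(ps.begin(), ps.end());
  S.pn.assign(pn.begin(), pn.end());
  S.cx.assign(cx.begin(), cx.end());
  S.cy.assign(cy.begin(), cy.end());
  S.cz.assign(cz.begin(), cz.end());
  S.pe.assign(pe.begin(), pe.end());
  S.pc.assign(pc.begin(), pc.end());
  S.nao = 0;
  for (int i = 0; i < S.nsh; ++i) {
    int nc = (S.l[i] + 1) * (S.l[i] + 2) / 2;
    S.ao_off.push_back(S.nao);
    S.ncomp.push_back(nc);
    S.nao += nc;
    if (S.l[i] > LMAX) stop("angular momentum above d is not supported");
  }
  return S;
}

// Cartesian component exponents in canonical order
static void comp_list(int l, int out[][3], int& n) {
  n = 0;
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly) {
      out[n][0] = lx; out[n][1] = ly; out[n][2] = l - lx - ly;
      ++n;
    }
}

// ---------------------------------------------------------------------------
// Kernel specification: rows of (kind, beta, coef); kind 0 = Coulomb,
// 1 = Gaussian, 2 = Gaussian-damped Coulomb.

struct Kernel {
  std::vector<int> kind;
  std::vector<double> beta, coef;
  int n;
};

static Kernel parse_kernel(NumericMatrix km) {
  Kernel k;
  k.n = km.nrow();
  for (int i = 0; i < k.n; ++i) {
    k.kind.push_back((int)km(i, 0));
    k.beta.push_back(km(i, 1));
    k.coef.push_back(km(i, 2));
  }
  return k;
}

// Auxiliary Hermite integrals A_n, n = 0..N (2^n d^n/dT^n of the base kernel),
// summed over kernel components.  Two-electron variant with bra exponent p and
// ket exponent q; T = |P-Q|^2.
static void aux_2e(const Kernel& k, int N, double p, double q, double T,
                   double* A) {
  double Fbuf[NMAX + 1], binom[NMAX + 1][NMAX + 1];
  for (int n = 0; n <= N; ++n) {
    binom[n][0] = 1.0;
    for (int j = 1; j <= n; ++j)
      binom[n][j] = binom[n - 1][j - 1] + (j <= n - 1 ? binom[n - 1][j] : 0.0);
    A[n] = 0.0;
  }
  double c = p + q;
  for (int ic = 0; ic < k.n; ++ic) {
    double coef = k.coef[ic], beta = k.beta[ic];
    if (k.kind[ic] == 0) {
      double omega = p * q / c;
      double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(c));
      boys_row(N, omega * T, Fbuf);
      double f = 1.0;
      for (int n = 0; n <= N; ++n) {
        A[n] += coef * pref * f * Fbuf[n];
        f *= -2.0 * omega;
      }
    } else if (k.kind[ic] == 1) {
      double D = p * q + beta * c;
      double theta = p * q * beta / D;
      double pref = std::pow(M_PI, 3.0) / std::pow(D, 1.5) *
                    std::exp(-theta * T);
      double f = 1.0;
      for (int n = 0; n <= N; ++n) {
        A[n] += coef * pref * f;
        f *= -2.0 * theta;
      }
    } else {
      double rho = p * q / c, nu = rho + beta;
      double a = rho * beta / nu, b = rho * rho / nu;
      double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(c)) *
                    (rho / nu) * std::exp(-a * T);
      boys_row(N, b * T, Fbuf);
      for (int n = 0; n <= N; ++n) {
        double s = 0.0, pa = 1.0;  // pa = (-2a)^(n-j) built downward
        for (int j = n; j >= 0; --j) {
          s += binom[n][j] * pa * std::pow(-2.0 * b, j) * Fbuf[j];
          pa *= -2.0 * a;
        }
        A[n] += coef * pref * s;
      }
    }
  }
}

// One-electron variant (grid/point kernels): bra exponent p, T = |P-C|^2.
static void aux_1e(const Kernel& k, int N, double p, double T, double* A) {
  double Fbuf[NMAX + 1], binom[NMAX + 1][NMAX + 1];
  for (int n = 0; n <= N; ++n) {
    binom[n][0] = 1.0;
    for (int j = 1; j <= n; ++j)
      binom[n][j] = binom[n - 1][j - 1] + (j <= n - 1 ? binom[n - 1][j] : 0.0);
    A[n] = 0.0;
  }
  for (int ic = 0; ic < k.n; ++ic) {
    double coef = k.coef[ic], beta = k.beta[ic];
    if (k.kind[ic] == 0) {
      double pref = 2.0 * M_PI / p;
      boys_row(N, p * T, Fbuf);
      double f = 1.0;
      for (int n = 0; n <= N; ++n) {
        A[n] += coef * pref * f * Fbuf[n];
        f *= -2.0 * p;
      }
    } else if (k.kind[ic] == 1) {
      double nu = p + beta, th = p * beta / nu;
      double pref = std::pow(M_PI / nu, 1.5) * std::exp(-th * T);
      double f = 1.0;
      for (int n = 0; n <= N; ++n) {
        A[n] += coef * pref * f;
        f *= -2.0 * th;
      }
    } else {
      double nu = p + beta;
      double a = p * beta / nu, b = p * p / nu;
      double pref = 2.0 * M_PI / nu * std::exp(-a * T);
      boys_row(N, b * T, Fbuf);
      for (int n = 0; n <= N; ++n) {
        double s = 0.0, pa = 1.0;
        for (int j = n; j >= 0; --j) {
          s += binom[n][j] * pa * std::pow(-2.0 * b, j) * Fbuf[j];
          pa *= -2.0 * a;
        }
        A[n] += coef * pref * s;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Hermite E coefficients (one dimension).  E[i][j][t] for i <= imax, j <= jmax.
struct ECoef {
  double e[EMAX + 1][EMAX + 1][2 * EMAX + 1];
};

static void build_E(int imax, int jmax, double a, double b, double AB,
                    ECoef& E) {
  double p = a + b, mu = a * b / p;
  double XPA = -b * AB / p, XPB = a * AB / p;  // P - A and P - B along this dim
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j)
      for (int t = 0; t <= 2 * EMAX; ++t) E.e[i][j][t] = 0.0;
  E.e[0][0][0] = std::exp(-mu * AB * AB);
  for (int i = 0; i < imax; ++i)
    for (int t = 0; t <= i + 1; ++t) {
      double v = 0.0;
      if (t > 0) v += E.e[i][0][t - 1] / (2.0 * p);
      v += XPA * E.e[i][0][t];
      v += (t + 1.0) * E.e[i][0][t + 1];
      E.e[i + 1][0][t] = v;
    }
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j < jmax; ++j)
      for (int t = 0; t <= i + j + 1; ++t) {
        double v = 0.0;
        if (t > 0) v += E.e[i][j][t - 1] / (2.0 * p);
        v += XPB * E.e[i][j][t];
        v += (t + 1.0) * E.e[i][j][t + 1];
        E.e[i][j + 1][t] = v;
      }
}

// ---------------------------------------------------------------------------
// Hermite R tensor from auxiliaries A_n at displacement (X, Y, Z).
struct RTens {
  double r[NMAX + 1][NMAX + 1][NMAX + 1];
};

static void build_R(int N, const double* A, double X, double Y, double Z,
                    RTens& R) {
  static thread_local double buf[NMAX + 1][NMAX + 1][NMAX + 1][NMAX + 1];
  for (int n = N; n >= 0; --n)
    for (int t = 0; t + n <= N; ++t)
      for (int u = 0; t + u + n <= N; ++u)
        for (int v = 0; t + u + v + n <= N; ++v) {
          double val;
          if (t == 0 && u == 0 && v == 0) {
            val = A[n];
          } else if (t > 0) {
            val = (t - 1 > 0 ? (t - 1) * buf[n + 1][t - 2][u][v] : 0.0) +
                  X * buf[n + 1][t - 1][u][v];
          } else if (u > 0) {
            val = (u - 1 > 0 ? (u - 1) * buf[n + 1][t][u - 2][v] : 0.0) +
                  Y * buf[n + 1][t][u - 1][v];
          } else {
            val = (v - 1 > 0 ? (v - 1) * buf[n + 1][t][u][v - 2] : 0.0) +
                  Z * buf[n + 1][t][u][v - 1];
          }
          buf[n][t][u][v] = val;
        }
  for (int t = 0; t <= N; ++t)
    for (int u = 0; t + u <= N; ++u)
      for (int v = 0; t + u + v <= N; ++v) R.r[t][u][v] = buf[0][t][u][v];
}

// ---------------------------------------------------------------------------
// Overlap and kinetic matrices

// [[Rcpp::export]]
List cpp_overlap_kinetic(List shellsA, List shellsB) {
  ShellSet A = parse_shells(shellsA), B = parse_shells(shellsB);
  NumericMatrix S(A.nao, B.nao), T(A.nao, B.nao);
  int ca[6][3], cb[6][3];
  for (int ia = 0; ia < A.nsh; ++ia) {
    int na; comp_list(A.l[ia], ca, na);
    for (int ib = 0; ib < B.nsh; ++ib) {
      int nb; comp_list(B.l[ib], cb, nb);
      double ABd[3] = {A.cx[ia] - B.cx[ib], A.cy[ia] - B.cy[ib],
                       A.cz[ia] - B.cz[ib]};
      for (int pa = 0; pa < A.pn[ia]; ++pa) {
        double ea = A.pe[A.ps[ia] + pa], caf = A.pc[A.ps[ia] + pa];
        for (int pb = 0; pb < B.pn[ib]; ++pb) {
          double eb = B.pe[B.ps[ib] + pb], cbf = B.pc[B.ps[ib] + pb];
          double p = ea + eb, cc = caf * cbf;
          double sp = std::sqrt(M_PI / p);
          ECoef Ex, Ey, Ez;
          build_E(A.l[ia], B.l[ib] + 2, ea, eb, ABd[0], Ex);
          build_E(A.l[ia], B.l[ib] + 2, ea, eb, ABd[1], Ey);
          build_E(A.l[ia], B.l[ib] + 2, ea, eb, ABd[2], Ez);
          for (int a = 0; a < na; ++a)
            for (int b = 0; b < nb; ++b) {
              double sx = Ex.e[ca[a][0]][cb[b][0]][0] * sp;
              double sy = Ey.e[ca[a][1]][cb[b][1]][0] * sp;
              double sz = Ez.e[ca[a][2]][cb[b][2]][0] * sp;
              // 1D kinetic blocks
              double kx, ky, kz;
              int j;
              j = cb[b][0];
              kx = -2.0 * eb * eb * Ex.e[ca[a][0]][j + 2][0] * sp +
                   eb * (2.0 * j + 1.0) * sx -
                   0.5 * j * (j - 1.0) * (j >= 2 ? Ex.e[ca[a][0]][j - 2][0] * sp : 0.0);
              j = cb[b][1];
              ky = -2.0 * eb * eb * Ey.e[ca[a][1]][j + 2][0] * sp +
                   eb * (2.0 * j + 1.0) * sy -
                   0.5 * j * (j - 1.0) * (j >= 2 ? Ey.e[ca[a][1]][j - 2][0] * sp : 0.0);
              j = cb[b][2];
              kz = -2.0 * eb * eb * Ez.e[ca[a][2]][j + 2][0] * sp +
                   eb * (2.0 * j + 1.0) * sz -
                   0.5 * j * (j - 1.0) * (j >= 2 ? Ez.e[ca[a][2]][j - 2][0] * sp : 0.0);
              S(A.ao_off[ia] + a, B.ao_off[ib] + b) += cc * sx * sy * sz;
              T(A.ao_off[ia] + a, B.ao_off[ib] + b) +=
                  cc * (kx * sy * sz + sx * ky * sz + sx * sy * kz);
            }
        }
      }
    }
  }
  return List::create(_["S"] = S, _["T"] = T);
}

// ---------------------------------------------------------------------------
// Grid-point one-electron kernel integrals (g|O|mu nu).
// Returns array (npts, naoA, naoB).  pairs: optional 0-based shell-pair matrix
// restricting which blocks are computed (others stay zero).

// [[Rcpp::export]]
NumericVector cpp_grid3c1e(List shellsA, List shellsB, NumericMatrix pts,
                           NumericMatrix kernelm, Nullable<IntegerMatrix> pairs) {
  ShellSet A = parse_shells(shellsA), B = parse_shells(shellsB);
  Kernel K = parse_kernel(kernelm);
  int ng = pts.nrow();
  NumericVector out(Dimension(ng, A.nao, B.nao));
  double* o = out.begin();
  int ca[6][3], cb[6][3];
  double Aux[NMAX + 1];
  RTens R;
  std::vector<std::pair<int, int> > plist;
  if (pairs.isNotNull()) {
    IntegerMatrix pm(pairs);
    for (int i = 0; i < pm.nrow(); ++i)
      plist.push_back(std::make_pair(pm(i, 0), pm(i, 1)));
  } else {
    for (int ia = 0; ia < A.nsh; ++ia)
      for (int ib = 0; ib < B.nsh; ++ib)
        plist.push_back(std::make_pair(ia, ib));
  }
  for (size_t ip = 0; ip < plist.size(); ++ip) {
    int ia = plist[ip].first, ib = plist[ip].second;
    int na, nb;
    comp_list(A.l[ia], ca, na);
    comp_list(B.l[ib], cb, nb);
    int N = A.l[ia] + B.l[ib];
    double ABd[3] = {A.cx[ia] - B.cx[ib], A.cy[ia] - B.cy[ib],
                     A.cz[ia] - B.cz[ib]};
    for (int pa = 0; pa < A.pn[ia]; ++pa) {
      double ea = A.pe[A.ps[ia] + pa], caf = A.pc[A.ps[ia] + pa];
      for (int pb = 0; pb < B.pn[ib]; ++pb) {
        double eb = B.pe[B.ps[ib] + pb], cbf = B.pc[B.ps[ib] + pb];
        double p = ea + eb, cc = caf * cbf;
        double P[3] = {(ea * A.cx[ia] + eb * B.cx[ib]) / p,
                       (ea * A.cy[ia] + eb * B.cy[ib]) / p,
                       (ea * A.cz[ia] + eb * B.cz[ib]) / p};
        ECoef Ex, Ey, Ez;
        build_E(A.l[ia], B.l[ib], ea, eb, ABd[0], Ex);
        build_E(A.l[ia], B.l[ib], ea, eb, ABd[1], Ey);
        build_E(A.l[ia], B.l[ib], ea, eb, ABd[2], Ez);
        for (int g = 0; g < ng; ++g) {
          double X = P[0] - pts(g, 0), Y = P[1] - pts(g, 1),
                 Z = P[2] - pts(g, 2);
          double T = X * X + Y * Y + Z * Z;
          aux_1e(K, N, p, T, Aux);
          build_R(N, Aux, X, Y, Z, R);
          for (int a = 0; a < na; ++a)
            for (int b = 0; b < nb; ++b) {
              double v = 0.0;
              for (int t = 0; t <= ca[a][0] + cb[b][0]; ++t)
                for (int u = 0; u <= ca[a][1] + cb[b][1]; ++u)
                  for (int w = 0; w <= ca[a][2] + cb[b][2]; ++w)
                    v += Ex.e[ca[a][0]][cb[b][0]][t] *
                         Ey.e[ca[a][1]][cb[b][1]][u] *
                         Ez.e[ca[a][2]][cb[b][2]][w] * R.r[t][u][w];
              o[g + ng * (A.ao_off[ia] + a) +
                (long)ng * A.nao * (B.ao_off[ib] + b)] += cc * v;
            }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// AO amplitudes on points: (npts, nao)

// [[Rcpp::export]]
NumericMatrix cpp_eval_aos(List shells, NumericMatrix pts) {
  ShellSet A = parse_shells(shells);
  int ng = pts.nrow();
  NumericMatrix out(ng, A.nao);
  int ca[6][3];
  for (int ia = 0; ia < A.nsh; ++ia) {
    int na;
    comp_list(A.l[ia], ca, na);
    for (int g = 0; g < ng; ++g) {
      double dx = pts(g, 0) - A.cx[ia], dy = pts(g, 1) - A.cy[ia],
             dz = pts(g, 2) - A.cz[ia];
      double r2 = dx * dx + dy * dy + dz * dz;
      double rad = 0.0;
      for (int pa = 0; pa < A.pn[ia]; ++pa)
        rad += A.pc[A.ps[ia] + pa] * std::exp(-A.pe[A.ps[ia] + pa] * r2);
      for (int a = 0; a < na; ++a) {
        double v = rad;
        for (int k = 0; k < ca[a][0]; ++k) v *= dx;
        for (int k = 0; k < ca[a][1]; ++k) v *= dy;
        for (int k = 0; k < ca[a][2]; ++k) v *= dz;
        out(g, A.ao_off[ia] + a) = v;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Generalized two-electron integrals (AB|O|CD) over four shell sets.
// Returns array (naoA, naoB, naoC, naoD).

// [[Rcpp::export]]
NumericVector cpp_eri(List shellsA, List shellsB, List shellsC, List shellsD,
                      NumericMatrix kernelm) {
  ShellSet A = parse_shells(shellsA), B = parse_shells(shellsB),
           C = parse_shells(shellsC), D = parse_shells(shellsD);
  Kernel K = parse_kernel(kernelm);
  NumericVector out((R_xlen_t)A.nao * B.nao * C.nao * D.nao);
  out.attr("dim") = IntegerVector::create(A.nao, B.nao, C.nao, D.nao);
  double* o = out.begin();
  long dA = A.nao, dAB = dA * B.nao, dABC = dAB * C.nao;
  int ca[6][3], cb[6][3], cc_[6][3], cd[6][3];
  double Aux[NMAX + 1];
  RTens R;
  for (int ia = 0; ia < A.nsh; ++ia) {
    int na; comp_list(A.l[ia], ca, na);
    for (int ib = 0; ib < B.nsh; ++ib) {
      int nb; comp_list(B.l[ib], cb, nb);
      int Lb = A.l[ia] + B.l[ib];
      double ABd[3] = {A.cx[ia] - B.cx[ib], A.cy[ia] - B.cy[ib],
                       A.cz[ia] - B.cz[ib]};
      for (int ic = 0; ic < C.nsh; ++ic) {
        int nc; comp_list(C.l[ic], cc_, nc);
        for (int id = 0; id < D.nsh; ++id) {
          int nd; comp_list(D.l[id], cd, nd);
          int Lk = C.l[ic] + D.l[id];
          int N = Lb + Lk;
          double CDd[3] = {C.cx[ic] - D.cx[id], C.cy[ic] - D.cy[id],
                           C.cz[ic] - D.cz[id]};
          for (int pa = 0; pa < A.pn[ia]; ++pa) {
            double ea = A.pe[A.ps[ia] + pa], fa = A.pc[A.ps[ia] + pa];
            for (int pb = 0; pb < B.pn[ib]; ++pb) {
              double eb = B.pe[B.ps[ib] + pb], fb = B.pc[B.ps[ib] + pb];
              double p = ea + eb;
              double P[3] = {(ea * A.cx[ia] + eb * B.cx[ib]) / p,
                             (ea * A.cy[ia] + eb * B.cy[ib]) / p,
                             (ea * A.cz[ia] + eb * B.cz[ib]) / p};
              ECoef Exb, Eyb, Ezb;
              build_E(A.l[ia], B.l[ib], ea, eb, ABd[0], Exb);
              build_E(A.l[ia], B.l[ib], ea, eb, ABd[1], Eyb);
              build_E(A.l[ia], B.l[ib], ea, eb, ABd[2], Ezb);
              for (int pc = 0; pc < C.pn[ic]; ++pc) {
                double ec = C.pe[C.ps[ic] + pc], fc = C.pc[C.ps[ic] + pc];
                for (int pd = 0; pd < D.pn[id]; ++pd) {
                  double ed = D.pe[D.ps[id] + pd], fd = D.pc[D.ps[id] + pd];
                  double q = ec + ed;
                  double Q[3] = {(ec * C.cx[ic] + ed * D.cx[id]) / q,
                                 (ec * C.cy[ic] + ed * D.cy[id]) / q,
                                 (ec * C.cz[ic] + ed * D.cz[id]) / q};
                  ECoef Exk, Eyk, Ezk;
                  build_E(C.l[ic], D.l[id], ec, ed, CDd[0], Exk);
                  build_E(C.l[ic], D.l[id], ec, ed, CDd[1], Eyk);
                  build_E(C.l[ic], D.l[id], ec, ed, CDd[2], Ezk);
                  double X = P[0] - Q[0], Y = P[1] - Q[1], Z = P[2] - Q[2];
                  double T = X * X + Y * Y + Z * Z;
                  aux_2e(K, N, p, q, T, Aux);
                  build_R(N, Aux, X, Y, Z, R);
                  double cfac = fa * fb * fc * fd;
                  for (int a = 0; a < na; ++a)
                    for (int b = 0; b < nb; ++b) {
                      int lx1 = ca[a][0] + cb[b][0], ly1 = ca[a][1] + cb[b][1],
                          lz1 = ca[a][2] + cb[b][2];
                      for (int c2 = 0; c2 < nc; ++c2)
                        for (int d2 = 0; d2 < nd; ++d2) {
                          int lx2 = cc_[c2][0] + cd[d2][0],
                              ly2 = cc_[c2][1] + cd[d2][1],
                              lz2 = cc_[c2][2] + cd[d2][2];
                          double v = 0.0;
                          for (int t = 0; t <= lx1; ++t) {
                            double ex = Exb.e[ca[a][0]][cb[b][0]][t];
                            if (ex == 0.0) continue;
                            for (int u = 0; u <= ly1; ++u) {
                              double exy = ex * Eyb.e[ca[a][1]][cb[b][1]][u];
                              if (exy == 0.0) continue;
                              for (int w = 0; w <= lz1; ++w) {
                                double exyz =
                                    exy * Ezb.e[ca[a][2]][cb[b][2]][w];
                                if (exyz == 0.0) continue;
                                for (int t2 = 0; t2 <= lx2; ++t2) {
                                  double ex2 =
                                      Exk.e[cc_[c2][0]][cd[d2][0]][t2];
                                  if (ex2 == 0.0) continue;
                                  for (int u2 = 0; u2 <= ly2; ++u2) {
                                    double exy2 =
                                        ex2 * Eyk.e[cc_[c2][1]][cd[d2][1]][u2];
                                    if (exy2 == 0.0) continue;
                                    for (int w2 = 0; w2 <= lz2; ++w2) {
                                      double e2 =
                                          exy2 *
                                          Ezk.e[cc_[c2][2]][cd[d2][2]][w2];
                                      if (e2 == 0.0) continue;
                                      double sgn =
                                          ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
                                      v += exyz * e2 * sgn *
                                           R.r[t + t2][u + u2][w + w2];
                                    }
                                  }
                                }
                              }
                            }
                          }
                          o[(A.ao_off[ia] + a) + dA * (B.ao_off[ib] + b) +
                            dAB * (C.ao_off[ic] + c2) +
                            dABC * (D.ao_off[id] + d2)] += cfac * v;
                        }
                    }
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Batched grid-wise product contraction:
//   E = sum_g w[g] sum_r sum_J sum_L W[g,J,L] * D[g, J + nJ*r] * C[g, L + nL*r]
// used by the hybrid DF+NQ product and U/T paths (element-wise in g, so not
// expressible as a single GEMM).

// [[Rcpp::export]]
double cpp_prod_exchange(NumericVector W, NumericMatrix D, NumericMatrix C,
                         NumericVector w, int nJ, int nL, int nR) {
  int ng = w.size();
  const double* Wp = W.begin();
  const double* Dp = D.begin();
  const double* Cp = C.begin();
  const double* wp = w.begin();
  double E = 0.0;
  for (int r = 0; r < nR; ++r)
    for (int L = 0; L < nL; ++L) {
      const double* c = Cp + (size_t)ng * (L + (size_t)nL * r);
      for (int J = 0; J < nJ; ++J) {
        const double* d = Dp + (size_t)ng * (J + (size_t)nJ * r);
        const double* ww = Wp + (size_t)ng * (J + (size_t)nJ * L);
        double s = 0.0;
        for (int g = 0; g < ng; ++g) s += wp[g] * ww[g] * d[g] * c[g];
        E += s;
      }
    }
  return E;
}
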