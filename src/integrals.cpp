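// McMurchie-Davidson evaluation of Gaussian AO integrals: overlap, kinetic,
// nuclear attraction, dipole, and two-electron repulsion integrals over
// contracted Cartesian shells.  Shells arrive from R as lists with fields
// l (angular momentum), exps, coefs (already primitive-normalized and
// contraction-scaled), center (bohr).  All matrices returned are in the raw
// Cartesian component basis; the R layer applies the solid-harmonic
// transformation and final per-AO normalization.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Shell {
  int l;
  std::vector<double> exps;
  std::vector<double> coefs;
  double cx, cy, cz;
  int ncart;  // (l+1)(l+2)/2
  int offset; // first Cartesian AO index
};

// Boys function F_0..F_n at x, stable for all x >= 0.
void boys(int nmax, double x, double* F) {
  if (x < 1e-13) {
    for (int m = 0; m <= nmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x > 35.0) {
    // upward recursion from the asymptotic F0; erf(sqrt x) ~ 1 here
    double ex = std::exp(-x);
    F[0] = 0.5 * std::sqrt(M_PI / x);
    for (int m = 0; m < nmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - ex) / (2.0 * x);
    return;
  }
  // series for F_nmax, then downward recursion
  double ex = std::exp(-x);
  double term = 1.0 / (2.0 * nmax + 1.0);
  double sum = term;
  for (int i = 1; i < 250; ++i) {
    term *= 2.0 * x / (2.0 * nmax + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[nmax] = ex * sum;
  for (int m = nmax; m > 0; --m)
    F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// Hermite expansion coefficients E_t^{ij} for one Cartesian direction.
// E is indexed [i][j][t]; includes the pair exponential prefactor in E_0^{00}.
struct ETab {
  int imax, jmax;
  std::vector<double> v; // (imax+1)*(jmax+1)*(imax+jmax+1)
  inline double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
  inline double& ref(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

void build_E(ETab& E, int imax, int jmax, double a, double b, double AB) {
  E.imax = imax; E.jmax = jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (imax + jmax + 1), 0.0);
  double p = a + b;
  double mu = a * b / p;
  double XPA = -b / p * AB * -1.0; // P - A = -(b/p)(A-B) ... see below
  // with AB = Ax - Bx: P = (aA + bB)/p, P - A = -(b/p) AB, P - B = (a/p) AB
  XPA = -(b / p) * AB;
  double XPB = (a / p) * AB;
  E.ref(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      if (j == 0) {
        for (int t = 0; t <= i + j; ++t)
          E.ref(i, j, t) = (1.0 / (2.0 * p)) * E.at(i - 1, j, t - 1)
                         + XPA * E.at(i - 1, j, t)
                         + (t + 1.0) * E.at(i - 1, j, t + 1);
      } else {
        for (int t = 0; t <= i + j; ++t)
          E.ref(i, j, t) = (1.0 / (2.0 * p)) * E.at(i, j - 1, t - 1)
                         + XPB * E.at(i, j - 1, t)
                         + (t + 1.0) * E.at(i, j - 1, t + 1);
      }
    }
  }
}

// Hermite Coulomb auxiliary R^0_{tuv}; builds full table R[t][u][v] at n=0.
struct RTab {
  int L;
  std::vector<double> v; // (L+1)^3, index (t*(L+1)+u)*(L+1)+v
  inline double at(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[(t * (L + 1) + u) * (L + 1) + w];
  }
};

struct RWork {
  std::vector<double> F;
  std::vector<std::vector<double>> Rn;
};

void build_R(RTab& R, int L, double p, double X, double Y, double Z, double scale,
             RWork* wk = nullptr) {
  R.L = L;
  int n1 = L + 1;
  R.v.assign(n1 * n1 * n1, 0.0);
  double T = p * (X * X + Y * Y + Z * Z);
  RWork local;
  if (!wk) wk = &local;
  wk->F.assign(L + 1, 0.0);
  std::vector<double>& F = wk->F;
  boys(L, T, F.data());
  // Rn[t][u][v] built by recursion over total order; keep all n slices
  // R^n_{000} = (-2p)^n F_n
  if ((int)wk->Rn.size() < L + 1) wk->Rn.resize(L + 1);
  std::vector<std::vector<double>>& Rn = wk->Rn;
  for (int n = 0; n <= L; ++n) {
    Rn[n].assign(n1 * n1 * n1, 0.0);
    double f = 1.0;
    for (int k = 0; k < n; ++k) f *= -2.0 * p;
    Rn[n][0] = f * F[n];
  }
  auto idx = [n1](int t, int u, int w) { return (t * n1 + u) * n1 + w; };
  for (int tot = 1; tot <= L; ++tot) {
    for (int t = 0; t <= tot; ++t)
      for (int u = 0; u + t <= tot; ++u) {
        int w = tot - t - u;
        for (int n = 0; n <= L - tot; ++n) {
          double val;
          if (t > 0) {
            val = X * Rn[n + 1][idx(t - 1, u, w)]
                + (t - 1 > 0 ? (t - 1) * Rn[n + 1][idx(t - 2, u, w)] : 0.0);
          } else if (u > 0) {
            val = Y * Rn[n + 1][idx(t, u - 1, w)]
                + (u - 1 > 0 ? (u - 1) * Rn[n + 1][idx(t, u - 2, w)] : 0.0);
          } else {
            val = Z * Rn[n + 1][idx(t, u, w - 1)]
                + (w - 1 > 0 ? (w - 1) * Rn[n + 1][idx(t, u, w - 2)] : 0.0);
          }
          Rn[n][idx(t, u, w)] = val;
        }
      }
  }
  for (size_t k = 0; k < R.v.size(); ++k) R.v[k] = scale * Rn[0][k];
}

// Cartesian components of shell l in fixed order (lx descending, then ly).
void cart_components(int l, std::vector<std::array<int,3>>& comp) {
  comp.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comp.push_back({lx, ly, l - lx - ly});
}

std::vector<Shell> parse_shells(const List& shells) {
  std::vector<Shell> S;
  int off = 0;
  for (int i = 0; i < shells.size(); ++i) {
    List sh = shells[i];
    Shell s;
    s.l = as<int>(sh["l"]);
    s.exps = as<std::vector<double>>(sh["exps"]);
    s.coefs = as<std::vector<double>>(sh["coefs"]);
    NumericVector c = sh["center"];
    s.cx = c[0]; s.cy = c[1]; s.cz = c[2];
    s.ncart = (s.l + 1) * (s.l + 2) / 2;
    s.offset = off;
    off += s.ncart;
    S.push_back(s);
  }
  return S;
}

int total_ncart(const std::vector<Shell>& S) {
  int n = 0;
  for (auto& s : S) n += s.ncart;
  return n;
}

} // namespace

// [[Rcpp::export]]
List cpp_one_electron(List shells_in, NumericMatrix nuc_coords,
                      NumericVector nuc_charges, NumericVector origin) {
  std::vector<Shell> S = parse_shells(shells_in);
  int n = total_ncart(S);
  NumericMatrix Sm(n, n), Tm(n, n), Vm(n, n), Dx(n, n), Dy(n, n), Dz(n, n);

  std::vector<std::array<int,3>> ca, cb;
  for (size_t A = 0; A < S.size(); ++A) {
    for (size_t B = 0; B <= A; ++B) {
      const Shell &sa = S[A], &sb = S[B];
      cart_components(sa.l, ca);
      cart_components(sb.l, cb);
      double ABx = sa.cx - sb.cx, ABy = sa.cy - sb.cy, ABz = sa.cz - sb.cz;
      int na = sa.ncart, nb = sb.ncart;
      std::vector<double> bS(na * nb, 0.0), bT(na * nb, 0.0), bV(na * nb, 0.0),
          bX(na * nb, 0.0), bY(na * nb, 0.0), bZ(na * nb, 0.0);
      for (size_t pa = 0; pa < sa.exps.size(); ++pa) {
        for (size_t pb = 0; pb < sb.exps.size(); ++pb) {
          double a = sa.exps[pa], b = sb.exps[pb];
          double cc = sa.coefs[pa] * sb.coefs[pb];
          double p = a + b;
          double Px = (a * sa.cx + b * sb.cx) / p;
          double Py = (a * sa.cy + b * sb.cy) / p;
          double Pz = (a * sa.cz + b * sb.cz) / p;
          // E tables per direction; need up to j+2 for kinetic
          ETab Ex, Ey, Ez;
          build_E(Ex, sa.l, sb.l + 2, a, b, ABx);
          build_E(Ey, sa.l, sb.l + 2, a, b, ABy);
          build_E(Ez, sa.l, sb.l + 2, a, b, ABz);
          double sp = std::sqrt(M_PI / p);
          double pref = sp * sp * sp; // (pi/p)^{3/2}
          // nuclear attraction Hermite table
          int Lab = sa.l + sb.l;
          for (int ia = 0; ia < na; ++ia) {
            for (int ib = 0; ib < nb; ++ib) {
              int ax = ca[ia][0], ay = ca[ia][1], az = ca[ia][2];
              int bx = cb[ib][0], by = cb[ib][1], bz = cb[ib][2];
              double sx = Ex.at(ax, bx, 0), sy = Ey.at(ay, by, 0), sz = Ez.at(az, bz, 0);
              bS[ia * nb + ib] += cc * pref * sx * sy * sz;
              // kinetic: 1D kinetic integrals
              auto kin1d = [&](const ETab& E, int i, int j, double sij) {
                double t = -2.0 * b * b * E.at(i, j + 2, 0)
                         + b * (2.0 * j + 1.0) * E.at(i, j, 0);
                if (j >= 2) t -= 0.5 * j * (j - 1.0) * E.at(i, j - 2, 0);
                (void)sij;
                return t;
              };
              double tx = kin1d(Ex, ax, bx, sx);
              double ty = kin1d(Ey, ay, by, sy);
              double tz = kin1d(Ez, az, bz, sz);
              bT[ia * nb + ib] += cc * pref * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
              // dipole about origin
              double dx = (Ex.at(ax, bx, 1) + (Px - origin[0]) * sx) * sy * sz;
              double dy = sx * (Ey.at(ay, by, 1) + (Py - origin[1]) * sy) * sz;
              double dz = sx * sy * (Ez.at(az, bz, 1) + (Pz - origin[2]) * sz);
              bX[ia * nb + ib] += cc * pref * dx;
              bY[ia * nb + ib] += cc * pref * dy;
              bZ[ia * nb + ib] += cc * pref * dz;
            }
          }
          // nuclear attraction
          for (int inuc = 0; inuc < nuc_coords.nrow(); ++inuc) {
            double X = Px - nuc_coords(inuc, 0);
            double Y = Py - nuc_coords(inuc, 1);
            double Z = Pz - nuc_coords(inuc, 2);
            RTab R;
            build_R(R, Lab, p, X, Y, Z, 1.0);
            double Zc = nuc_charges[inuc];
            for (int ia = 0; ia < na; ++ia) {
              for (int ib = 0; ib < nb; ++ib) {
                int ax = ca[ia][0], ay = ca[ia][1], az = ca[ia][2];
                int bx = cb[ib][0], by = cb[ib][1], bz = cb[ib][2];
                double acc = 0.0;
                for (int t = 0; t <= ax + bx; ++t) {
                  double ex = Ex.at(ax, bx, t);
                  if (ex == 0.0) continue;
                  for (int u = 0; u <= ay + by; ++u) {
                    double ey = Ey.at(ay, by, u);
                    if (ey == 0.0) continue;
                    for (int w = 0; w <= az + bz; ++w) {
                      double ez = Ez.at(az, bz, w);
                      if (ez == 0.0) continue;
                      acc += ex * ey * ez * R.at(t, u, w);
                    }
                  }
                }
                bV[ia * nb + ib] += -Zc * cc * (2.0 * M_PI / p) * acc;
              }
            }
          }
        }
      }
      for (int ia = 0; ia < na; ++ia) {
        for (int ib = 0; ib < nb; ++ib) {
          int I = sa.offset + ia, J = sb.offset + ib;
          Sm(I, J) = Sm(J, I) = bS[ia * nb + ib];
          Tm(I, J) = Tm(J, I) = bT[ia * nb + ib];
          Vm(I, J) = Vm(J, I) = bV[ia * nb + ib];
          Dx(I, J) = Dx(J, I) = bX[ia * nb + ib];
          Dy(I, J) = Dy(J, I) = bY[ia * nb + ib];
          Dz(I, J) = Dz(J, I) = bZ[ia * nb + ib];
        }
      }
    }
  }
  return List::create(_["S"] = Sm, _["T"] = Tm, _["V"] = Vm,
                      _["DX"] = Dx, _["DY"] = Dy, _["DZ"] = Dz);
}

namespace {

// Flattened Hermite coefficient vectors for one primitive pair of a
// shell pair, per Cartesian component pair.
struct HermiteDist {
  int L1;              // lA+lB+1 per direction
  int ncomp;           // na*nb
  std::vector<double> coef; // ncomp x L1^3
};

// Precomputed primitive-pair data for a shell pair.
struct PairPrim {
  double p;          // a + b
  double Px, Py, Pz; // gaussian product center
  double cc;         // coefficient product
  double bound;      // |cc| exp(-mu r^2) (pi/p)^{3/2}, crude magnitude
  ETab Ex, Ey, Ez;
};

struct ShellPair {
  int A, B;
  std::vector<PairPrim> prims;
  std::vector<HermiteDist> hd; // one per primitive pair, built once
};

void build_hermite_dist(const Shell& sa, const Shell& sb, const PairPrim& pp,
                        HermiteDist& hd);

void build_pair(const Shell& sa, const Shell& sb, ShellPair& sp) {
  double ABx = sa.cx - sb.cx, ABy = sa.cy - sb.cy, ABz = sa.cz - sb.cz;
  double r2 = ABx * ABx + ABy * ABy + ABz * ABz;
  for (size_t pa = 0; pa < sa.exps.size(); ++pa) {
    for (size_t pb = 0; pb < sb.exps.size(); ++pb) {
      double a = sa.exps[pa], b = sb.exps[pb];
      double mu = a * b / (a + b);
      double cc = sa.coefs[pa] * sb.coefs[pb];
      if (std::abs(cc) * std::exp(-mu * r2) < 1e-16) continue;
      PairPrim pp;
      pp.p = a + b;
      pp.Px = (a * sa.cx + b * sb.cx) / pp.p;
      pp.Py = (a * sa.cy + b * sb.cy) / pp.p;
      pp.Pz = (a * sa.cz + b * sb.cz) / pp.p;
      pp.cc = cc;
      pp.bound = std::abs(cc) * std::exp(-mu * r2) *
                 std::pow(M_PI / pp.p, 1.5);
      build_E(pp.Ex, sa.l, sb.l, a, b, ABx);
      build_E(pp.Ey, sa.l, sb.l, a, b, ABy);
      build_E(pp.Ez, sa.l, sb.l, a, b, ABz);
      sp.prims.push_back(pp);
    }
  }
  sp.hd.resize(sp.prims.size());
  for (size_t k = 0; k < sp.prims.size(); ++k)
    build_hermite_dist(sa, sb, sp.prims[k], sp.hd[k]);
}

void build_hermite_dist(const Shell& sa, const Shell& sb, const PairPrim& pp,
                        HermiteDist& hd) {
  std::vector<std::array<int,3>> ca, cb;
  cart_components(sa.l, ca);
  cart_components(sb.l, cb);
  int L1 = sa.l + sb.l + 1;
  hd.L1 = L1;
  hd.ncomp = sa.ncart * sb.ncart;
  hd.coef.assign((size_t)hd.ncomp * L1 * L1 * L1, 0.0);
  for (int ia = 0; ia < sa.ncart; ++ia)
    for (int ib = 0; ib < sb.ncart; ++ib) {
      int ax = ca[ia][0], ay = ca[ia][1], az = ca[ia][2];
      int bx = cb[ib][0], by = cb[ib][1], bz = cb[ib][2];
      double* dst = &hd.coef[(size_t)(ia * sb.ncart + ib) * L1 * L1 * L1];
      for (int t = 0; t <= ax + bx; ++t) {
        double ex = pp.Ex.at(ax, bx, t);
        if (ex == 0.0) continue;
        for (int u = 0; u <= ay + by; ++u) {
          double exy = ex * pp.Ey.at(ay, by, u);
          if (exy == 0.0) continue;
          for (int w = 0; w <= az + bz; ++w) {
            double e = exy * pp.Ez.at(az, bz, w);
            if (e != 0.0) dst[(t * L1 + u) * L1 + w] = e;
          }
        }
      }
    }
}

} // namespace

// Two-electron integrals over spherical-harmonic AOs: Cartesian shell
// quartets are evaluated with McMurchie-Davidson and transformed to the
// (normalized) solid-harmonic basis per quartet with the per-shell
// coefficient blocks supplied by the R layer.
// [[Rcpp::export]]
NumericVector cpp_eri(List shells_in, List c2s, double screen_tol = 1e-12) {
  std::vector<Shell> S = parse_shells(shells_in);
  int nsh = S.size();
  // spherical transforms and offsets
  std::vector<NumericMatrix> T;
  std::vector<int> soff(nsh), snum(nsh);
  int nsph = 0;
  for (int i = 0; i < nsh; ++i) {
    NumericMatrix Ti = c2s[i];
    T.push_back(Ti);
    soff[i] = nsph;
    snum[i] = Ti.nrow();
    nsph += Ti.nrow();
  }
  int n = nsph;
  NumericVector out((R_xlen_t)n * n * n * n);
  double* eri = out.begin();
  auto put = [&](int i, int j, int k, int l, double v) {
    size_t N = n;
    eri[((size_t)l * N * N * N) + ((size_t)k * N * N) + ((size_t)j * N) + i] = v;
  };

  // shell pairs (A >= B)
  std::vector<ShellPair> pairs;
  for (int A = 0; A < nsh; ++A)
    for (int B = 0; B <= A; ++B) {
      ShellPair sp; sp.A = A; sp.B = B;
      build_pair(S[A], S[B], sp);
      pairs.push_back(sp);
    }

  // Schwarz bounds per shell pair: sqrt(max |(ab|ab)|)
  int npair = pairs.size();
  std::vector<double> schwarz(npair, 0.0);

  // generic quartet kernel; writes block values into buf (na*nb*nc*nd)
  std::vector<double> buf;
  auto quartet = [&](const ShellPair& sp1, const ShellPair& sp2) {
    const Shell &sa = S[sp1.A], &sb = S[sp1.B], &sc = S[sp2.A], &sd = S[sp2.B];
    int na = sa.ncart, nb = sb.ncart, nc = sc.ncart, nd = sd.ncart;
    buf.assign((size_t)na * nb * nc * nd, 0.0);
    int Lab = sa.l + sb.l, Lcd = sc.l + sd.l;
    int L = Lab + Lcd;
    int L1ab = Lab + 1, L1cd = Lcd + 1, L1 = L + 1;
    std::vector<double> G; // per (cd) component: Hermite rep over ab side
    static RTab R;
    static RWork rwork;
    for (size_t ipa = 0; ipa < sp1.prims.size(); ++ipa) {
      const PairPrim& pa = sp1.prims[ipa];
      const HermiteDist& hab = sp1.hd[ipa];
      for (size_t ipb = 0; ipb < sp2.prims.size(); ++ipb) {
        const PairPrim& pb = sp2.prims[ipb];
        const HermiteDist& hcd = sp2.hd[ipb];
        double alpha = pa.p * pb.p / (pa.p + pb.p);
        double X = pa.Px - pb.Px, Y = pa.Py - pb.Py, Z = pa.Pz - pb.Pz;
        double pref = 2.0 * std::pow(M_PI, 2.5) /
                      (pa.p * pb.p * std::sqrt(pa.p + pb.p));
        pref *= pa.cc * pb.cc;
        if (pa.bound * pb.bound * 20.0 < screen_tol * 1e-2) continue;
        build_R(R, L, alpha, X, Y, Z, 1.0, &rwork);
        // G[cdcomp][(t,u,v)_ab] = sum_{t'u'v'} (-1)^{t'+u'+v'} Ecd * R[t+t',...]
        G.assign((size_t)hcd.ncomp * L1ab * L1ab * L1ab, 0.0);
        for (int c2 = 0; c2 < hcd.ncomp; ++c2) {
          const double* ecd = &hcd.coef[(size_t)c2 * L1cd * L1cd * L1cd];
          double* g = &G[(size_t)c2 * L1ab * L1ab * L1ab];
          for (int t2 = 0; t2 < L1cd; ++t2)
            for (int u2 = 0; u2 < L1cd; ++u2)
              for (int w2 = 0; w2 < L1cd; ++w2) {
                double e = ecd[(t2 * L1cd + u2) * L1cd + w2];
                if (e == 0.0) continue;
                double sgn = ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
                double se = sgn * e;
                for (int t1 = 0; t1 < L1ab; ++t1)
                  for (int u1 = 0; u1 < L1ab; ++u1)
                    for (int w1 = 0; w1 < L1ab; ++w1)
                      g[(t1 * L1ab + u1) * L1ab + w1] +=
                          se * R.v[((t1 + t2) * L1 + (u1 + u2)) * L1 + (w1 + w2)];
              }
        }
        // contract with ab side
        for (int c1 = 0; c1 < hab.ncomp; ++c1) {
          const double* eab = &hab.coef[(size_t)c1 * L1ab * L1ab * L1ab];
          for (int c2 = 0; c2 < hcd.ncomp; ++c2) {
            const double* g = &G[(size_t)c2 * L1ab * L1ab * L1ab];
            double acc = 0.0;
            int m = L1ab * L1ab * L1ab;
            for (int k = 0; k < m; ++k) acc += eab[k] * g[k];
            buf[(size_t)c1 * hcd.ncomp + c2] += pref * acc;
          }
        }
      }
    }
  };

  for (int ip = 0; ip < npair; ++ip) {
    quartet(pairs[ip], pairs[ip]);
    const Shell &sa = S[pairs[ip].A], &sb = S[pairs[ip].B];
    int na = sa.ncart, nb = sb.ncart;
    double mx = 0.0;
    for (int ia = 0; ia < na; ++ia)
      for (int ib = 0; ib < nb; ++ib) {
        int c = ia * nb + ib;
        double v = buf[(size_t)c * na * nb + c];
        if (std::abs(v) > mx) mx = std::abs(v);
      }
    schwarz[ip] = std::sqrt(mx);
  }

  // transform one index of a dense block: out[s, rest] = sum_c T[s,c] in[c, rest]
  // works on the leading index; cycling four times covers all indices
  std::vector<double> tbuf;
  auto sph_transform = [&](std::vector<double>& blk, int A1, int B1, int C1, int D1,
                           int iA, int iB, int iC, int iD) {
    // successive leading-index transforms with cyclic rotation
    // blk layout: [a (slowest), b, c, d (fastest)] as in quartet kernel
    int dims[4] = {A1, B1, C1, D1};
    int ish[4] = {iA, iB, iC, iD};
    for (int step = 0; step < 4; ++step) {
      const NumericMatrix& Ts = T[ish[0]];
      int nc = Ts.ncol(), ns = Ts.nrow();
      int rest = 1;
      for (int k2 = 1; k2 < 4; ++k2) rest *= dims[k2];
      tbuf.assign((size_t)ns * rest, 0.0);
      for (int c = 0; c < nc; ++c) {
        const double* src = &blk[(size_t)c * rest];
        for (int s2 = 0; s2 < ns; ++s2) {
          double w = Ts(s2, c);
          if (w == 0.0) continue;
          double* dst = &tbuf[(size_t)s2 * rest];
          for (int r = 0; r < rest; ++r) dst[r] += w * src[r];
        }
      }
      // rotate: move transformed leading index to the back
      blk.assign((size_t)rest * ns, 0.0);
      for (int s2 = 0; s2 < ns; ++s2)
        for (int r = 0; r < rest; ++r)
          blk[(size_t)r * ns + s2] = tbuf[(size_t)s2 * rest + r];
      int d0 = ns;
      dims[0] = dims[1]; dims[1] = dims[2]; dims[2] = dims[3]; dims[3] = d0;
      int s0 = ish[0];
      ish[0] = ish[1]; ish[1] = ish[2]; ish[2] = ish[3]; ish[3] = s0;
    }
  };

  std::vector<double> sblk;
  for (int ip = 0; ip < npair; ++ip) {
    for (int jp = 0; jp <= ip; ++jp) {
      if (schwarz[ip] * schwarz[jp] < screen_tol) continue;
      quartet(pairs[ip], pairs[jp]);
      int iA = pairs[ip].A, iB = pairs[ip].B, iC = pairs[jp].A, iD = pairs[jp].B;
      const Shell &sa = S[iA], &sb = S[iB], &sc = S[iC], &sd = S[iD];
      sblk = buf;
      sph_transform(sblk, sa.ncart, sb.ncart, sc.ncart, sd.ncart, iA, iB, iC, iD);
      int nb2 = snum[iB], nc2 = snum[iC], nd2 = snum[iD];
      for (int ia = 0; ia < snum[iA]; ++ia)
        for (int ib = 0; ib < nb2; ++ib)
          for (int ic = 0; ic < nc2; ++ic)
            for (int id = 0; id < nd2; ++id) {
              double v = sblk[(((size_t)ia * nb2 + ib) * nc2 + ic) * nd2 + id];
              int I = soff[iA] + ia, J = soff[iB] + ib;
              int K = soff[iC] + ic, Ld = soff[iD] + id;
              put(I, J, K, Ld, v); put(J, I, K, Ld, v);
              put(I, J, Ld, K, v); put(J, I, Ld, K, v);
              put(K, Ld, I, J, v); put(Ld, K, I, J, v);
              put(K, Ld, J, I, v); put(Ld, K, J, I, v);
            }
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// Pivoted incomplete Cholesky of a PSD matrix M (n x n), stopping when the
// largest remaining diagonal element is <= tol.  Returns n x rank matrix.
// [[Rcpp::export]]
NumericMatrix cpp_pivoted_cholesky(NumericMatrix M, double tol, int maxrank) {
  int n = M.nrow();
  if (maxrank <= 0 || maxrank > n) maxrank = n;
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) d[i] = M(i, i);
  std::vector<std::vector<double>> cols; // selected columns of L
  std::vector<int> piv;
  for (int k = 0; k < maxrank; ++k) {
    int p = 0;
    double dmax = d[0];
    for (int i = 1; i < n; ++i) if (d[i] > dmax) { dmax = d[i]; p = i; }
    if (dmax <= tol) break;
    std::vector<double> col(n);
    for (int i = 0; i < n; ++i) col[i] = M(i, p);
    for (int j = 0; j < k; ++j) {
      double ljp = cols[j][p];
      if (ljp == 0.0) continue;
      const double* cj = cols[j].data();
      for (int i = 0; i < n; ++i) col[i] -= ljp * cj[i];
    }
    double s = std::sqrt(dmax);
    for (int i = 0; i < n; ++i) col[i] /= s;
    col[p] = s;
    for (int i = 0; i < n; ++i) d[i] -= col[i] * col[i];
    d[p] = 0.0;
    cols.push_back(std::move(col));
    piv.push_back(p + 1);
  }
  int rank = cols.size();
  NumericMatrix L(n, std::max(rank, 1));
  if (rank == 0) { NumericMatrix L0(n, 0); return L0; }
  for (int j = 0; j < rank; ++j)
    for (int i = 0; i < n; ++i) L(i, j) = cols[j][i];
  L.attr("pivots") = wrap(piv);
  return L;
}

// Generalized two-tensor contraction kernel used by the R-level einsum:
// permutes A to (free, contracted) layout and B to (contracted, free),
// multiplies with BLAS dgemm, and permutes the result to the requested
// output order.  Scratch buffers persist across calls to avoid R-level
// allocation churn in the iterative solvers.
#include <R_ext/BLAS.h>

namespace {

// out[ j ] = in[ i ] with index permutation: out dim d_out = d_in[perm];
// single pass over the input with precomputed output strides
void permute_into(const double* in, const int* d_in, int nd,
                  const int* perm, std::vector<double>& out) {
  const int MAXD = 8;
  if (nd > MAXD) Rcpp::stop("permute_into: too many dimensions");
  size_t total = 1;
  for (int k = 0; k < nd; ++k) total *= d_in[k];
  out.resize(total);
  if (nd == 1) { std::copy(in, in + total, out.data()); return; }
  // output dims and strides (column-major)
  int d_out[MAXD];
  size_t str_out[MAXD];
  for (int k = 0; k < nd; ++k) d_out[k] = d_in[perm[k] - 1];
  size_t s = 1;
  for (int k = 0; k < nd; ++k) { str_out[k] = s; s *= d_out[k]; }
  // for input axis a, its stride in the output layout
  size_t str_for_in[MAXD];
  for (int k = 0; k < nd; ++k) str_for_in[perm[k] - 1] = str_out[k];
  int D[MAXD]; size_t S[MAXD];
  for (int k = 0; k < MAXD; ++k) {
    D[k] = k < nd ? d_in[k] : 1;
    S[k] = k < nd ? str_for_in[k] : 0;
  }
  const double* p = in;
  for (int i7 = 0; i7 < D[7]; ++i7)
  for (int i6 = 0; i6 < D[6]; ++i6)
  for (int i5 = 0; i5 < D[5]; ++i5)
  for (int i4 = 0; i4 < D[4]; ++i4)
  for (int i3 = 0; i3 < D[3]; ++i3)
  for (int i2 = 0; i2 < D[2]; ++i2)
  for (int i1 = 0; i1 < D[1]; ++i1) {
    double* o = out.data() + i1 * S[1] + i2 * S[2] + i3 * S[3] +
                i4 * S[4] + i5 * S[5] + i6 * S[6] + i7 * S[7];
    for (int i0 = 0; i0 < D[0]; ++i0) o[i0 * S[0]] = *p++;
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_contract(NumericVector A, IntegerVector da, IntegerVector pa,
                           NumericVector B, IntegerVector db, IntegerVector pb,
                           int m, int k, int n, IntegerVector dres,
                           IntegerVector pout) {
  static std::vector<double> bufA, bufB, bufC;
  // A -> (fa..., con...) layout, B -> (con..., fb...)
  bool idA = true, idB = true;
  for (int i = 0; i < pa.size(); ++i) if (pa[i] != i + 1) idA = false;
  for (int i = 0; i < pb.size(); ++i) if (pb[i] != i + 1) idB = false;
  const double* Ap;
  const double* Bp;
  if (idA) Ap = A.begin();
  else { permute_into(A.begin(), da.begin(), da.size(), pa.begin(), bufA); Ap = bufA.data(); }
  if (idB) Bp = B.begin();
  else { permute_into(B.begin(), db.begin(), db.size(), pb.begin(), bufB); Bp = bufB.data(); }
  bufC.resize((size_t)m * n);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, Ap, &m, Bp, &k, &zero,
                  bufC.data(), &m FCONE FCONE);
  bool idO = true;
  for (int i = 0; i < pout.size(); ++i) if (pout[i] != i + 1) idO = false;
  NumericVector out((R_xlen_t)m * n);
  if (idO) {
    std::copy(bufC.begin(), bufC.end(), out.begin());
  } else {
    static std::vector<double> bufO;
    permute_into(bufC.data(), dres.begin(), dres.size(), pout.begin(), bufO);
    std::copy(bufO.begin(), bufO.end(), out.begin());
  }
  return out;
}
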