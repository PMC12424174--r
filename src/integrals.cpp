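// Gaussian integral engine (McMurchie-Davidson scheme) over contracted
// Cartesian shells, plus dense linear-algebra helpers used by the solvers.
// Conventions: integrals in atomic units (bohr, hartree); ERIs returned in
// chemists' notation (mu nu | la si) with 8-fold permutational symmetry,
// packed over canonical pair indices.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(double T, int mmax, double* F) {
  const double SQRTPIO2 = 0.88622692545275801365;  // sqrt(pi)/2
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m)
      F[m] = 1.0 / (2.0 * m + 1.0) - T / (2.0 * m + 3.0);
    return;
  }
  if (T > 35.0) {  // e^{-T} below double precision
    F[0] = SQRTPIO2 / std::sqrt(T);
    for (int m = 1; m <= mmax; ++m) F[m] = F[m - 1] * (2.0 * m - 1.0) / (2.0 * T);
    return;
  }
  double expT = std::exp(-T);
  double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
  for (int k = 1; k < 500; ++k) {
    term *= (2.0 * T) / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < sum * 1e-17) break;
  }
  F[mmax] = expT * sum;
  for (int m = mmax - 1; m >= 0; --m)
    F[m] = (2.0 * T * F[m + 1] + expT) / (2.0 * m + 1.0);
}

// --------------------------------------------- Hermite expansion coefficients
// E[t + (LMAX1)*(i + LMAX1*j)] for one Cartesian direction.
struct ECoef {
  int la, lb, nt;
  std::vector<double> e;  // (la+1) x (lb+1) x (la+lb+1)
  double& at(int i, int j, int t) { return e[(size_t)t + (size_t)(la + lb + 1) * (i + (size_t)(la + 1) * j)]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return e[(size_t)t + (size_t)(la + lb + 1) * (i + (size_t)(la + 1) * j)];
  }
};

static void build_E(ECoef& E, int la, int lb, double a, double b, double AB) {
  E.la = la; E.lb = lb; E.nt = la + lb;
  E.e.assign((size_t)(la + 1) * (lb + 1) * (la + lb + 1), 0.0);
  double p = a + b, q = a * b / p;
  E.at(0, 0, 0) = std::exp(-q * AB * AB);
  double PA = -b * AB / p;  // P - A with AB = A - B
  double PB = a * AB / p;   // P - B
  for (int i = 0; i <= la; ++i) {
    for (int j = 0; j <= lb; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double v;
        if (j == 0) {  // decrement i
          v = E.get(i - 1, j, t - 1) / (2.0 * p) + PA * E.get(i - 1, j, t) +
              (t + 1) * E.get(i - 1, j, t + 1);
        } else {       // decrement j
          v = E.get(i, j - 1, t - 1) / (2.0 * p) + PB * E.get(i, j - 1, t) +
              (t + 1) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = v;
      }
    }
  }
}

// ------------------------------------------------------- Hermite Coulomb R_tuv
// R[t][u][v] at order 0, via intermediate orders.
struct RTens {
  int L;
  std::vector<double> r;  // (L+1)^3
  double& at(int t, int u, int v) { return r[(size_t)t + (size_t)(L + 1) * (u + (size_t)(L + 1) * v)]; }
  double get(int t, int u, int v) const {
    if (t < 0 || u < 0 || v < 0) return 0.0;
    return r[(size_t)t + (size_t)(L + 1) * (u + (size_t)(L + 1) * v)];
  }
};

static void build_R(RTens& R, int L, double alpha, double X, double Y, double Z) {
  R.L = L;
  R.r.assign((size_t)(L + 1) * (L + 1) * (L + 1), 0.0);
  double T = alpha * (X * X + Y * Y + Z * Z);
  std::vector<double> F(L + 1);
  boys(T, L, F.data());
  // R^n_{000} = (-2 alpha)^n F_n
  std::vector<double> Fn(L + 1);
  double fac = 1.0;
  for (int n = 0; n <= L; ++n) { Fn[n] = fac * F[n]; fac *= -2.0 * alpha; }
  // iterate orders downward: maintain R^n for n = L..0
  // store R^{n} in a cube, build from R^{n+1}
  std::vector<RTens> Rn(L + 1);
  for (int n = L; n >= 0; --n) {
    Rn[n].L = L - n;
    Rn[n].r.assign((size_t)(L - n + 1) * (L - n + 1) * (L - n + 1), 0.0);
    Rn[n].at(0, 0, 0) = Fn[n];
    for (int t = 0; t <= L - n; ++t)
      for (int u = 0; u <= L - n - t; ++u)
        for (int v = 0; v <= L - n - t - u; ++v) {
          if (t + u + v == 0) continue;
          double val;
          if (t > 0) {
            val = (t - 1) * Rn[n + 1].get(t - 2, u, v) + X * Rn[n + 1].get(t - 1, u, v);
          } else if (u > 0) {
            val = (u - 1) * Rn[n + 1].get(t, u - 2, v) + Y * Rn[n + 1].get(t, u - 1, v);
          } else {
            val = (v - 1) * Rn[n + 1].get(t, u, v - 2) + Z * Rn[n + 1].get(t, u, v - 1);
          }
          Rn[n].at(t, u, v) = val;
        }
  }
  R.r = Rn[0].r;
}

// ------------------------------------------------------------- shell handling
struct Shell {
  int l;
  arma::vec exps, coefs;  // coefs already include primitive (l,0,0) norms
  double cx, cy, cz;
};

static std::vector<Shell> parse_shells(const List& shells) {
  int ns = shells.size();
  std::vector<Shell> sh(ns);
  for (int i = 0; i < ns; ++i) {
    List s = shells[i];
    sh[i].l = as<int>(s["l"]);
    sh[i].exps = as<arma::vec>(s["exps"]);
    sh[i].coefs = as<arma::vec>(s["coefs"]);
    arma::vec c = as<arma::vec>(s["center"]);
    sh[i].cx = c[0]; sh[i].cy = c[1]; sh[i].cz = c[2];
  }
  return sh;
}

static int ncart(int l) { return (l + 1) * (l + 2) / 2; }

// Cartesian component list for angular momentum l (lexicographic, x first)
static void cart_comps(int l, std::vector<std::array<int,3>>& c) {
  c.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      c.push_back({lx, ly, l - lx - ly});
}

// -------------------------------------------------- one-electron integrals
// kind: 0 overlap, 1 kinetic
// [[Rcpp::export(rng = false)]]
arma::mat cpp_one_electron(List shellList, int kind) {
  std::vector<Shell> sh = parse_shells(shellList);
  int ns = sh.size();
  std::vector<int> off(ns + 1, 0);
  for (int i = 0; i < ns; ++i) off[i + 1] = off[i] + ncart(sh[i].l);
  int nao = off[ns];
  arma::mat M(nao, nao, arma::fill::zeros);
  for (int I = 0; I < ns; ++I) {
    std::vector<std::array<int,3>> ca; cart_comps(sh[I].l, ca);
    for (int J = 0; J <= I; ++J) {
      std::vector<std::array<int,3>> cb; cart_comps(sh[J].l, cb);
      double ABx = sh[I].cx - sh[J].cx, ABy = sh[I].cy - sh[J].cy, ABz = sh[I].cz - sh[J].cz;
      arma::mat block(ca.size(), cb.size(), arma::fill::zeros);
      for (arma::uword pa = 0; pa < sh[I].exps.n_elem; ++pa) {
        for (arma::uword pb = 0; pb < sh[J].exps.n_elem; ++pb) {
          double a = sh[I].exps[pa], b = sh[J].exps[pb];
          double p = a + b;
          double cc = sh[I].coefs[pa] * sh[J].coefs[pb];
          double pref = cc * std::pow(M_PI / p, 1.5);
          // E coefficients with extended angular momentum for kinetic
          int ext = (kind == 1) ? 2 : 0;
          ECoef Ex, Ey, Ez;
          build_E(Ex, sh[I].l, sh[J].l + ext, a, b, ABx);
          build_E(Ey, sh[I].l, sh[J].l + ext, a, b, ABy);
          build_E(Ez, sh[I].l, sh[J].l + ext, a, b, ABz);
          for (size_t ia = 0; ia < ca.size(); ++ia) {
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              int i = ca[ia][0], k = ca[ia][1], m = ca[ia][2];
              int j = cb[ib][0], l2 = cb[ib][1], n = cb[ib][2];
              if (kind == 0) {
                block(ia, ib) += pref * Ex.get(i, j, 0) * Ey.get(k, l2, 0) * Ez.get(m, n, 0);
              } else {
                // kinetic via angular-momentum shifted overlaps per direction
                auto Sx = [&](int jj) { return (jj < 0) ? 0.0 : Ex.get(i, jj, 0); };
                auto Sy = [&](int jj) { return (jj < 0) ? 0.0 : Ey.get(k, jj, 0); };
                auto Sz = [&](int jj) { return (jj < 0) ? 0.0 : Ez.get(m, jj, 0); };
                double Tx = -2.0 * b * b * Sx(j + 2) + b * (2.0 * j + 1.0) * Sx(j) -
                            0.5 * j * (j - 1.0) * Sx(j - 2);
                double Ty = -2.0 * b * b * Sy(l2 + 2) + b * (2.0 * l2 + 1.0) * Sy(l2) -
                            0.5 * l2 * (l2 - 1.0) * Sy(l2 - 2);
                double Tz = -2.0 * b * b * Sz(n + 2) + b * (2.0 * n + 1.0) * Sz(n) -
                            0.5 * n * (n - 1.0) * Sz(n - 2);
                block(ia, ib) += pref * (Tx * Sy(l2) * Sz(n) + Sx(j) * Ty * Sz(n) + Sx(j) * Sy(l2) * Tz);
              }
            }
          }
        }
      }
      M.submat(off[I], off[J], off[I] + ca.size() - 1, off[J] + cb.size() - 1) = block;
      if (I != J)
        M.submat(off[J], off[I], off[J] + cb.size() - 1, off[I] + ca.size() - 1) = block.t();
    }
  }
  return M;
}

// nuclear attraction to a set of point charges (positions ncent x 3, charges)
// [[Rcpp::export(rng = false)]]
arma::mat cpp_nuclear(List shellList, arma::mat centers, arma::vec charges) {
  std::vector<Shell> sh = parse_shells(shellList);
  int ns = sh.size();
  std::vector<int> off(ns + 1, 0);
  for (int i = 0; i < ns; ++i) off[i + 1] = off[i] + ncart(sh[i].l);
  int nao = off[ns];
  arma::mat M(nao, nao, arma::fill::zeros);
  for (int I = 0; I < ns; ++I) {
    std::vector<std::array<int,3>> ca; cart_comps(sh[I].l, ca);
    for (int J = 0; J <= I; ++J) {
      std::vector<std::array<int,3>> cb; cart_comps(sh[J].l, cb);
      double ABx = sh[I].cx - sh[J].cx, ABy = sh[I].cy - sh[J].cy, ABz = sh[I].cz - sh[J].cz;
      int L = sh[I].l + sh[J].l;
      arma::mat block(ca.size(), cb.size(), arma::fill::zeros);
      for (arma::uword pa = 0; pa < sh[I].exps.n_elem; ++pa) {
        for (arma::uword pb = 0; pb < sh[J].exps.n_elem; ++pb) {
          double a = sh[I].exps[pa], b = sh[J].exps[pb];
          double p = a + b;
          double Px = (a * sh[I].cx + b * sh[J].cx) / p;
          double Py = (a * sh[I].cy + b * sh[J].cy) / p;
          double Pz = (a * sh[I].cz + b * sh[J].cz) / p;
          double cc = sh[I].coefs[pa] * sh[J].coefs[pb];
          double pref = cc * 2.0 * M_PI / p;
          ECoef Ex, Ey, Ez;
          build_E(Ex, sh[I].l, sh[J].l, a, b, ABx);
          build_E(Ey, sh[I].l, sh[J].l, a, b, ABy);
          build_E(Ez, sh[I].l, sh[J].l, a, b, ABz);
          for (arma::uword ic = 0; ic < charges.n_elem; ++ic) {
            RTens R;
            build_R(R, L, p, Px - centers(ic, 0), Py - centers(ic, 1), Pz - centers(ic, 2));
            for (size_t ia = 0; ia < ca.size(); ++ia) {
              for (size_t ib = 0; ib < cb.size(); ++ib) {
                int i = ca[ia][0], k = ca[ia][1], m = ca[ia][2];
                int j = cb[ib][0], l2 = cb[ib][1], n = cb[ib][2];
                double s = 0.0;
                for (int t = 0; t <= i + j; ++t)
                  for (int u = 0; u <= k + l2; ++u)
                    for (int v = 0; v <= m + n; ++v)
                      s += Ex.get(i, j, t) * Ey.get(k, l2, u) * Ez.get(m, n, v) * R.get(t, u, v);
                block(ia, ib) += -charges[ic] * pref * s;
              }
            }
          }
        }
      }
      M.submat(off[I], off[J], off[I] + ca.size() - 1, off[J] + cb.size() - 1) = block;
      if (I != J)
        M.submat(off[J], off[I], off[J] + cb.size() - 1, off[I] + ca.size() - 1) = block.t();
    }
  }
  return M;
}

// ----------------------------------------------------------------- ERI engine
static inline size_t pidx(size_t i, size_t j) {  // canonical pair index, i>=j
  return i * (i + 1) / 2 + j;
}

// Hermite charge distribution for a contracted shell pair: for every
// primitive pair store prefactor and E products; evaluated on the fly below.

// [[Rcpp::export(rng = false)]]
NumericVector cpp_eri(List shellList, double screen_tol) {
  std::vector<Shell> sh = parse_shells(shellList);
  int ns = sh.size();
  std::vector<int> off(ns + 1, 0);
  for (int i = 0; i < ns; ++i) off[i + 1] = off[i] + ncart(sh[i].l);
  size_t nao = off[ns];
  size_t npair = nao * (nao + 1) / 2;
  NumericVector out((R_xlen_t)(npair * (npair + 1) / 2));
  double* eri = out.begin();

  std::vector<std::vector<std::array<int,3>>> comps(ns);
  for (int i = 0; i < ns; ++i) cart_comps(sh[i].l, comps[i]);

  // Schwarz bounds per shell pair
  arma::mat schwarz(ns, ns, arma::fill::zeros);

  // helper evaluating a full shell quartet block into `block`
  auto quartet = [&](int I, int J, int K, int L, std::vector<double>& block) {
    int nI = comps[I].size(), nJ = comps[J].size(), nK = comps[K].size(), nL = comps[L].size();
    block.assign((size_t)nI * nJ * nK * nL, 0.0);
    int Lab = sh[I].l + sh[J].l, Lcd = sh[K].l + sh[L].l, Ltot = Lab + Lcd;
    double ABx = sh[I].cx - sh[J].cx, ABy = sh[I].cy - sh[J].cy, ABz = sh[I].cz - sh[J].cz;
    double CDx = sh[K].cx - sh[L].cx, CDy = sh[K].cy - sh[L].cy, CDz = sh[K].cz - sh[L].cz;
    for (arma::uword pa = 0; pa < sh[I].exps.n_elem; ++pa)
      for (arma::uword pb = 0; pb < sh[J].exps.n_elem; ++pb) {
        double a = sh[I].exps[pa], b = sh[J].exps[pb], p = a + b;
        double Px = (a * sh[I].cx + b * sh[J].cx) / p;
        double Py = (a * sh[I].cy + b * sh[J].cy) / p;
        double Pz = (a * sh[I].cz + b * sh[J].cz) / p;
        ECoef E1x, E1y, E1z;
        build_E(E1x, sh[I].l, sh[J].l, a, b, ABx);
        build_E(E1y, sh[I].l, sh[J].l, a, b, ABy);
        build_E(E1z, sh[I].l, sh[J].l, a, b, ABz);
        double cab = sh[I].coefs[pa] * sh[J].coefs[pb];
        for (arma::uword pc = 0; pc < sh[K].exps.n_elem; ++pc)
          for (arma::uword pd = 0; pd < sh[L].exps.n_elem; ++pd) {
            double c = sh[K].exps[pc], d = sh[L].exps[pd], q = c + d;
            double Qx = (c * sh[K].cx + d * sh[L].cx) / q;
            double Qy = (c * sh[K].cy + d * sh[L].cy) / q;
            double Qz = (c * sh[K].cz + d * sh[L].cz) / q;
            ECoef E2x, E2y, E2z;
            build_E(E2x, sh[K].l, sh[L].l, c, d, CDx);
            build_E(E2y, sh[K].l, sh[L].l, c, d, CDy);
            build_E(E2z, sh[K].l, sh[L].l, c, d, CDz);
            double alpha = p * q / (p + q);
            RTens R;
            build_R(R, Ltot, alpha, Px - Qx, Py - Qy, Pz - Qz);
            double pref = cab * sh[K].coefs[pc] * sh[L].coefs[pd] *
                          2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
            size_t idx = 0;
            for (int ia = 0; ia < nI; ++ia)
              for (int ib = 0; ib < nJ; ++ib)
                for (int ic = 0; ic < nK; ++ic)
                  for (int id = 0; id < nL; ++id, ++idx) {
                    int i1 = comps[I][ia][0], k1 = comps[I][ia][1], m1 = comps[I][ia][2];
                    int j1 = comps[J][ib][0], l1 = comps[J][ib][1], n1 = comps[J][ib][2];
                    int i2 = comps[K][ic][0], k2 = comps[K][ic][1], m2 = comps[K][ic][2];
                    int j2 = comps[L][id][0], l2 = comps[L][id][1], n2 = comps[L][id][2];
                    double s = 0.0;
                    for (int t1 = 0; t1 <= i1 + j1; ++t1) {
                      double ex1 = E1x.get(i1, j1, t1);
                      if (ex1 == 0.0) continue;
                      for (int u1 = 0; u1 <= k1 + l1; ++u1) {
                        double ey1 = E1y.get(k1, l1, u1);
                        if (ey1 == 0.0) continue;
                        for (int v1 = 0; v1 <= m1 + n1; ++v1) {
                          double ez1 = E1z.get(m1, n1, v1);
                          if (ez1 == 0.0) continue;
                          double w1 = ex1 * ey1 * ez1;
                          double s2 = 0.0;
                          for (int t2 = 0; t2 <= i2 + j2; ++t2) {
                            double ex2 = E2x.get(i2, j2, t2);
                            if (ex2 == 0.0) continue;
                            for (int u2 = 0; u2 <= k2 + l2; ++u2) {
                              double ey2 = E2y.get(k2, l2, u2);
                              if (ey2 == 0.0) continue;
                              for (int v2 = 0; v2 <= m2 + n2; ++v2) {
                                double ez2 = E2z.get(m2, n2, v2);
                                if (ez2 == 0.0) continue;
                                double sgn = ((t2 + u2 + v2) % 2) ? -1.0 : 1.0;
                                s2 += sgn * ex2 * ey2 * ez2 * R.get(t1 + t2, u1 + u2, v1 + v2);
                              }
                            }
                          }
                          s += w1 * s2;
                        }
                      }
                    }
                    block[idx] += pref * s;
                  }
          }
      }
  };

  std::vector<double> block;
  // Schwarz: sqrt((IJ|IJ)) max over components
  for (int I = 0; I < ns; ++I)
    for (int J = 0; J <= I; ++J) {
      quartet(I, J, I, J, block);
      int nI = comps[I].size(), nJ = comps[J].size();
      double mx = 0.0;
      for (int ia = 0; ia < nI; ++ia)
        for (int ib = 0; ib < nJ; ++ib) {
          double v = block[((size_t)(ia * nJ + ib)) * nI * nJ + (size_t)ia * nJ + ib];
          if (v > mx) mx = v;
        }
      schwarz(I, J) = schwarz(J, I) = std::sqrt(std::max(mx, 0.0));
    }

  for (int I = 0; I < ns; ++I)
    for (int J = 0; J <= I; ++J) {
      for (int K = 0; K <= I; ++K)
        for (int L = 0; L <= ((K == I) ? J : K); ++L) {
          if (schwarz(I, J) * schwarz(K, L) < screen_tol) continue;
          quartet(I, J, K, L, block);
          int nI = comps[I].size(), nJ = comps[J].size(), nK = comps[K].size(), nL = comps[L].size();
          size_t idx = 0;
          for (int ia = 0; ia < nI; ++ia)
            for (int ib = 0; ib < nJ; ++ib)
              for (int ic = 0; ic < nK; ++ic)
                for (int id = 0; id < nL; ++id, ++idx) {
                  size_t mu = off[I] + ia, nu = off[J] + ib, la = off[K] + ic, si = off[L] + id;
                  size_t ij = (mu >= nu) ? pidx(mu, nu) : pidx(nu, mu);
                  size_t kl = (la >= si) ? pidx(la, si) : pidx(si, la);
                  size_t g = (ij >= kl) ? pidx(ij, kl) : pidx(kl, ij);
                  eri[g] = block[idx];
                }
        }
    }
  return out;
}

// ------------------------------------------------ generic 4-index transform
// T[i,j,k,l] = sum_{mu nu la si} (mu nu|la si) C1[mu,i] C2[nu,j] C3[la,k] C4[si,l]
// Returns a flat array in column-major order over (i,j,k,l).
// [[Rcpp::export(rng = false)]]
// unpack the 8-fold packed ERI store into the full (mu,nu,si,la) square
// [[Rcpp::export(rng = false)]]
arma::mat cpp_unpack_eri(NumericVector eri, int nao) {
  size_t n = nao;
  const double* g = eri.begin();
  arma::mat G((size_t)n * n, (size_t)n * n);
  for (size_t la = 0; la < n; ++la)
    for (size_t si = 0; si <= la; ++si) {
      size_t kl = pidx(la, si);
      double* colA = G.colptr(si + n * la);
      double* colB = G.colptr(la + n * si);
      for (size_t mu = 0; mu < n; ++mu) {
        size_t base = pidx(mu, 0);
        for (size_t nu = 0; nu <= mu; ++nu) {
          size_t ij = base + nu;
          double v = g[(ij >= kl) ? pidx(ij, kl) : pidx(kl, ij)];
          colA[mu + n * nu] = v;
          colA[nu + n * mu] = v;
          if (si != la) {
            colB[mu + n * nu] = v;
            colB[nu + n * mu] = v;
          }
        }
      }
    }
  return G;
}

// [[Rcpp::export(rng = false)]]
arma::vec cpp_transform_eri_g(const arma::mat& G0, int nao, arma::mat C1,
                              arma::mat C2, arma::mat C3, arma::mat C4) {
  size_t n = nao;
  int n1 = C1.n_cols, n2 = C2.n_cols, n3 = C3.n_cols, n4 = C4.n_cols;
  // layout of G is (mu, nu, si, la): columns indexed si + n*la.
  arma::mat G;  // unused placeholder (kept so later G.reset() is harmless)
  // view (mu,nu,si) x la and contract la with C3
  arma::mat W1;
  {
    const arma::mat Gv(const_cast<double*>(G0.memptr()), (size_t)n * n * n, n,
                       false, true);
    W1 = Gv * C3;            // (mu, nu, si) x k
  }
  G.reset();
  // reorder (mu,nu,si,k) -> ((mu,nu,k), si) and contract si with C4
  arma::mat W2((size_t)n * n * n3, n);
  {
    size_t nn = (size_t)n * n;
    for (int k2 = 0; k2 < n3; ++k2)
      for (size_t si = 0; si < n; ++si)
        std::memcpy(W2.colptr(si) + (size_t)k2 * nn,
                    W1.colptr(k2) + si * nn, sizeof(double) * nn);
  }
  W1.reset();
  arma::mat W3 = W2 * C4;    // (mu, nu, k) x l
  W2.reset();
  // contract mu: view n x (nu, k, l)
  arma::mat W4;
  {
    arma::mat W3v(W3.memptr(), n, (size_t)n * n3 * n4, false, true);
    W4 = C1.t() * W3v;       // i x (nu, k, l)
  }
  W3.reset();
  // reorder (i, nu, k, l) -> ((i,k,l), nu) and contract nu with C2
  arma::mat W5((size_t)n1 * n3 * n4, n);
  for (int l2 = 0; l2 < n4; ++l2)
    for (int k2 = 0; k2 < n3; ++k2)
      for (size_t nu = 0; nu < n; ++nu) {
        const double* src = W4.colptr(nu + (size_t)n * k2 + (size_t)n * n3 * l2);
        double* dst = W5.colptr(nu) + (size_t)n1 * (k2 + (size_t)n3 * l2);
        std::memcpy(dst, src, sizeof(double) * n1);
      }
  W4.reset();
  arma::mat W6 = W5 * C2;    // (i, k, l) x j
  W5.reset();
  arma::vec T4((size_t)n1 * n2 * n3 * n4);
  for (int j = 0; j < n2; ++j)
    for (int l2 = 0; l2 < n4; ++l2)
      for (int k2 = 0; k2 < n3; ++k2) {
        const double* src = W6.colptr(j) + (size_t)n1 * (k2 + (size_t)n3 * l2);
        double* dst = T4.memptr() + (size_t)n1 * j +
              (size_t)n1 * n2 * k2 + (size_t)n1 * n2 * n3 * l2;
        std::memcpy(dst, src, sizeof(double) * n1);
      }
  return T4;  // column-major (i,j,k,l)
}

// ------------------------------------------------------ Coulomb/exchange build
// J[a,b] = sum_{cd} (ab|cd) D[c,d];  K[p,q] = sum_{rs} (pr|qs) D[r,s]
// D need not be symmetric.
// [[Rcpp::export(rng = false)]]
List cpp_jk(NumericVector eri, int nao, arma::mat D) {
  size_t n = nao;
  const double* g = eri.begin();
  arma::mat J(n, n, arma::fill::zeros), K(n, n, arma::fill::zeros);
  const double* d = D.memptr();
  double* j = J.memptr();
  double* k = K.memptr();
  auto contrib = [&](size_t A, size_t B, size_t C, size_t Dd, double v) {
    j[A + n * B] += v * d[C + n * Dd];
    k[A + n * C] += v * d[B + n * Dd];
  };
  for (size_t mu = 0; mu < n; ++mu)
    for (size_t nu = 0; nu <= mu; ++nu) {
      size_t ij = pidx(mu, nu);
      bool b_eq = (mu == nu);
      for (size_t la = 0; la <= mu; ++la) {
        size_t simax = (la == mu) ? nu : la;
        for (size_t si = 0; si <= simax; ++si) {
          size_t kl = pidx(la, si);
          double v = g[pidx(ij, kl)];
          if (v == 0.0) continue;
          bool k_eq = (la == si), bk_eq = (ij == kl);
          contrib(mu, nu, la, si, v);
          if (!b_eq) contrib(nu, mu, la, si, v);
          if (!k_eq) {
            contrib(mu, nu, si, la, v);
            if (!b_eq) contrib(nu, mu, si, la, v);
          }
          if (!bk_eq) {
            contrib(la, si, mu, nu, v);
            if (!k_eq) contrib(si, la, mu, nu, v);
            if (!b_eq) {
              contrib(la, si, nu, mu, v);
              if (!k_eq) contrib(si, la, nu, mu, v);
            }
          }
        }
      }
    }
  return List::create(_["J"] = J, _["K"] = K);
}

// --------------------------------------- 2-electron singlet FCI (pair basis)
// Orthonormal spatial orbitals 1..n; basis functions are symmetrized pairs
// (p<=q). H built from one-electron matrix h and mo ERIs (chemists, full
// array flat column-major n^4: g[p + n q + n^2 r + n^3 s] = (pq|rs)).
// [[Rcpp::export(rng = false)]]
arma::mat cpp_fci2_hamiltonian(arma::mat h, arma::vec g, int n) {
  int npair = n * (n + 1) / 2;
  arma::mat H(npair, npair);
  auto G = [&](int p, int q, int r, int s) {
    return g[(size_t)p + (size_t)n * q + (size_t)n * n * r + (size_t)n * n * n * s];
  };
  std::vector<int> P(npair), Q(npair);
  int c = 0;
  for (int p = 0; p < n; ++p)
    for (int q = p; q < n; ++q) { P[c] = p; Q[c] = q; ++c; }
  for (int A = 0; A < npair; ++A) {
    int p = P[A], q = Q[A];
    double na = (p == q) ? 2.0 : 1.0;
    for (int B = 0; B <= A; ++B) {
      int r = P[B], s = Q[B];
      double nb = (r == s) ? 2.0 : 1.0;
      // <pq|H|rs> for ordered products
      double t1 = (q == s ? h(p, r) : 0.0) + (p == r ? h(q, s) : 0.0) + G(p, r, q, s);
      double t2 = (q == r ? h(p, s) : 0.0) + (p == s ? h(q, r) : 0.0) + G(p, s, q, r);
      double v = (t1 + t2) / std::sqrt(na * nb);
      H(A, B) = v;
      H(B, A) = v;
    }
  }
  return H;
}

// Davidson for lowest nroots of a dense symmetric matrix.
// [[Rcpp::export(rng = false)]]
List cpp_davidson(arma::mat& H, int nroots, double tol, int maxiter) {
  int n = H.n_rows;
  if (n <= 1400 || nroots * 12 >= n) {
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, H);
    int k = std::min(nroots, n);
    return List::create(_["values"] = eval.head(k), _["vectors"] = evec.cols(0, k - 1));
  }
  arma::vec hd = H.diag();
  int nb = std::min(2 * nroots + 4, n);
  arma::mat V(n, 0);
  // unit guesses on smallest diagonal entries
  arma::uvec ord = arma::sort_index(hd);
  arma::mat guess(n, nb, arma::fill::zeros);
  for (int i = 0; i < nb; ++i) guess(ord[i], i) = 1.0;
  V = guess;
  arma::mat AV;
  for (int it = 0; it < maxiter; ++it) {
    // orthonormalize V
    arma::mat Qm, Rm;
    arma::qr_econ(Qm, Rm, V);
    V = Qm;
    AV = H * V;
    arma::mat Hs = V.t() * AV;
    Hs = 0.5 * (Hs + Hs.t());
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, Hs);
    arma::mat X = V * evec.cols(0, nroots - 1);
    arma::mat AX = AV * evec.cols(0, nroots - 1);
    arma::mat Rres = AX - X * arma::diagmat(eval.head(nroots));
    double rmax = arma::abs(Rres).max();
    if (rmax < tol || (int)V.n_cols > std::min(n, 30 * nroots + 60)) {
      return List::create(_["values"] = eval.head(nroots), _["vectors"] = X);
    }
    // augment with preconditioned residuals
    arma::mat add(n, nroots);
    for (int r = 0; r < nroots; ++r) {
      arma::vec d = hd - eval[r];
      d.transform([](double x) { return (std::abs(x) < 1e-6) ? 1e-6 : x; });
      add.col(r) = Rres.col(r) / d;
    }
    V = arma::join_rows(V, add);
  }
  // fallback: return current best
  arma::mat Qm, Rm;
  arma::qr_econ(Qm, Rm, V);
  V = Qm;
  AV = H * V;
  arma::mat Hs = V.t() * AV;
  Hs = 0.5 * (Hs + Hs.t());
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, Hs);
  arma::mat X = V * evec.cols(0, nroots - 1);
  return List::create(_["values"] = eval.head(nroots), _["vectors"] = X);
}
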