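// Determinant-space kernels: k-RDMs from CI expansions and the exact
// oracle (literal application of the second-quantized exchange strings on
// tensor products of monomer CI expansions).  Determinants are bitmasks
// over spinorbitals (1..n alpha, n+1..2n beta => bits 0..2n-1), ordered
// ascending; |det> = a+_{o1} a+_{o2} ... |0> with o1 < o2 < ...

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int parity_below(uint32_t mask, int p) {
  // number of set bits below position p (0-based)
  uint32_t below = mask & ((1u << p) - 1u);
  return __builtin_popcount(below) & 1;
}

// annihilate orbital p (0-based); returns false if empty; sign in *sgn
static inline bool ann(uint32_t& mask, int p, int& sgn) {
  if (!(mask & (1u << p))) return false;
  if (parity_below(mask, p)) sgn = -sgn;
  mask &= ~(1u << p);
  return true;
}

static inline bool cre(uint32_t& mask, int p, int& sgn) {
  if (mask & (1u << p)) return false;
  if (parity_below(mask, p)) sgn = -sgn;
  mask |= (1u << p);
  return true;
}

// enumerate ordered k-tuples of set bits of mask into out (each tuple k ints)
static void ordered_tuples(uint32_t mask, int k, std::vector<std::array<int,3>>& out) {
  std::vector<int> bits;
  for (int p = 0; p < 32; ++p) if (mask & (1u << p)) bits.push_back(p);
  out.clear();
  int nb = bits.size();
  if (k == 1) {
    for (int a = 0; a < nb; ++a) out.push_back({bits[a], 0, 0});
  } else if (k == 2) {
    for (int a = 0; a < nb; ++a)
      for (int b = 0; b < nb; ++b)
        if (a != b) out.push_back({bits[a], bits[b], 0});
  } else if (k == 3) {
    for (int a = 0; a < nb; ++a)
      for (int b = 0; b < nb; ++b)
        for (int c = 0; c < nb; ++c)
          if (a != b && a != c && b != c) out.push_back({bits[a], bits[b], bits[c]});
  }
}

// ---------------------------------------------------------------- ci_rdms
// [[Rcpp::export(rng = false)]]
List cpp_ci_rdms(IntegerVector detmask, NumericVector coef, int m, int kmax) {
  int nd = detmask.size();
  std::unordered_map<uint32_t, int> lookup;
  for (int i = 0; i < nd; ++i) lookup[(uint32_t)detmask[i]] = i;
  arma::mat G1(m, m, arma::fill::zeros);
  arma::vec G2, G3;
  if (kmax >= 2) G2.zeros((size_t)m * m * m * m);
  if (kmax >= 3) G3.zeros((size_t)m * m * m * m * m * m);
  std::vector<std::array<int,3>> qts, pts;
  for (int k = 1; k <= kmax; ++k) {
    for (int J = 0; J < nd; ++J) {
      double cJ = coef[J];
      if (cJ == 0.0) continue;
      uint32_t mJ = (uint32_t)detmask[J];
      ordered_tuples(mJ, k, qts);
      for (auto& qt : qts) {
        uint32_t m1 = mJ;
        int s1 = 1;
        bool ok = true;
        for (int i = 0; i < k && ok; ++i) ok = ann(m1, qt[i], s1);
        if (!ok) continue;
        // creators over all spinorbitals not in m1
        uint32_t avail = (~m1) & ((m == 32) ? 0xffffffffu : ((1u << m) - 1u));
        ordered_tuples(avail, k, pts);
        for (auto& pt : pts) {
          uint32_t m2 = m1;
          int s2 = s1;
          bool ok2 = true;
          for (int i = k - 1; i >= 0 && ok2; --i) ok2 = cre(m2, pt[i], s2);
          if (!ok2) continue;
          auto it = lookup.find(m2);
          if (it == lookup.end()) continue;
          double w = coef[it->second] * cJ * s2;
          if (w == 0.0) continue;
          if (k == 1) G1(pt[0], qt[0]) += w;
          else if (k == 2)
            G2[(size_t)pt[0] + (size_t)m * pt[1] + (size_t)m * m * qt[0] +
               (size_t)m * m * m * qt[1]] += w;
          else
            G3[(size_t)pt[0] + (size_t)m * pt[1] + (size_t)m * m * pt[2] +
               (size_t)m * m * m * qt[0] + (size_t)m * m * m * m * qt[1] +
               (size_t)m * m * m * m * m * qt[2]] += w;
        }
      }
    }
  }
  List out = List::create(_["G1"] = G1);
  if (kmax >= 2) out["G2"] = G2;
  if (kmax >= 3) out["G3"] = G3;
  return out;
}

// ------------------------------------------------------------ product state
// state: parallel vectors maskA, maskB, coef
typedef std::unordered_map<uint64_t, double> StateMap;

static inline uint64_t pairkey(uint32_t a, uint32_t b) {
  return ((uint64_t)a << 32) | (uint64_t)b;
}

// [[Rcpp::export(rng = false)]]
List cpp_apply_P2k(IntegerVector maskA, IntegerVector maskB, NumericVector coef,
                   int k, arma::mat S) {
  // S: spinorbital overlap, rows = A spinorbitals (mA), cols = B (mB)
  int mA = S.n_rows, mB = S.n_cols;
  double pref = ((k % 2) ? -1.0 : 1.0);
  for (int i = 0; i < k; ++i) pref /= (double)(i + 1) * (i + 1);
  StateMap out;
  std::vector<std::array<int,3>> qts, sts;
  // dressed creator application: returns expansion as (mask, amp) pairs
  struct Br { uint32_t mask; double amp; };
  std::vector<Br> curA, nxtA, curB, nxtB;
  int n = maskA.size();
  for (int e = 0; e < n; ++e) {
    uint32_t mAocc = (uint32_t)maskA[e], mBocc = (uint32_t)maskB[e];
    double c0 = coef[e];
    ordered_tuples(mAocc, k, qts);
    ordered_tuples(mBocc, k, sts);
    for (auto& qt : qts) {
      uint32_t a1 = mAocc;
      int sA = 1;
      bool ok = true;
      for (int i = 0; i < k && ok; ++i) ok = ann(a1, qt[i], sA);
      if (!ok) continue;
      for (auto& st : sts) {
        uint32_t b1 = mBocc;
        int sB = 1;
        bool ok2 = true;
        for (int i = 0; i < k && ok2; ++i) ok2 = ann(b1, st[i], sB);
        if (!ok2) continue;
        double base = pref * c0 * sA * sB;
        // A creators: ctilde+_{s_1} ... ctilde+_{s_k}, rightmost (s_k) first
        curA.clear();
        curA.push_back({a1, 1.0});
        for (int i = k - 1; i >= 0; --i) {
          nxtA.clear();
          int scol = st[i];
          for (auto& br : curA)
            for (int p = 0; p < mA; ++p) {
              double w = S(p, scol);
              if (w == 0.0) continue;
              uint32_t mm = br.mask;
              int sg = 1;
              if (!cre(mm, p, sg)) continue;
              nxtA.push_back({mm, br.amp * w * sg});
            }
          curA.swap(nxtA);
          if (curA.empty()) break;
        }
        if (curA.empty()) continue;
        // B creators: dtilde+_{q_1} ... dtilde+_{q_k}, rightmost (q_k) first
        curB.clear();
        curB.push_back({b1, 1.0});
        for (int i = k - 1; i >= 0; --i) {
          nxtB.clear();
          int qrow = qt[i];
          for (auto& br : curB)
            for (int r = 0; r < mB; ++r) {
              double w = S(qrow, r);
              if (w == 0.0) continue;
              uint32_t mm = br.mask;
              int sg = 1;
              if (!cre(mm, r, sg)) continue;
              nxtB.push_back({mm, br.amp * w * sg});
            }
          curB.swap(nxtB);
          if (curB.empty()) break;
        }
        if (curB.empty()) continue;
        for (auto& ea : curA)
          for (auto& eb : curB) {
            double v = base * ea.amp * eb.amp;
            if (v != 0.0) out[pairkey(ea.mask, eb.mask)] += v;
          }
      }
    }
  }
  int no = out.size();
  IntegerVector oA(no), oB(no);
  NumericVector oc(no);
  int i = 0;
  for (auto& kv : out) {
    oA[i] = (int)(kv.first >> 32);
    oB[i] = (int)(kv.first & 0xffffffffu);
    oc[i] = kv.second;
    ++i;
  }
  return List::create(_["maskA"] = oA, _["maskB"] = oB, _["coef"] = oc);
}

// inner product of two states given as mask/coef vectors
// [[Rcpp::export(rng = false)]]
double cpp_state_dot(IntegerVector mA1, IntegerVector mB1, NumericVector c1,
                     IntegerVector mA2, IntegerVector mB2, NumericVector c2) {
  StateMap s2;
  for (int i = 0; i < mA2.size(); ++i)
    s2[pairkey((uint32_t)mA2[i], (uint32_t)mB2[i])] += c2[i];
  double tot = 0;
  for (int i = 0; i < mA1.size(); ++i) {
    auto it = s2.find(pairkey((uint32_t)mA1[i], (uint32_t)mB1[i]));
    if (it != s2.end()) tot += c1[i] * it->second;
  }
  return tot;
}

// sparse <I|a+_p a_q|J> for monomer determinants: fills tp/tq/ts vectors
static bool t1_sparse(uint32_t mI, uint32_t mJ, std::vector<int>& tp,
                      std::vector<int>& tq, std::vector<int>& tsgn) {
  tp.clear(); tq.clear(); tsgn.clear();
  uint32_t dI = mI & ~mJ, dJ = mJ & ~mI;
  int nI = __builtin_popcount(dI), nJ = __builtin_popcount(dJ);
  if (nJ > 1 || nI != nJ) return nJ == 0 && nI == 0 ? true : false;
  if (nJ == 1) {
    int q = __builtin_ctz(dJ), p = __builtin_ctz(dI);
    uint32_t mm = mJ;
    int sg = 1;
    ann(mm, q, sg);
    if (!cre(mm, p, sg)) return false;
    if (mm != mI) return false;
    tp.push_back(p); tq.push_back(q); tsgn.push_back(sg);
    return true;
  }
  for (int p = 0; p < 32; ++p)
    if (mI & (1u << p)) { tp.push_back(p); tq.push_back(p); tsgn.push_back(1); }
  return true;
}

// <bra| V |ket> with V = sum vt[p,q,r,s] a^p_q b^r_s (vt flat column-major
// over dims mA,mA,mB,mB)
// [[Rcpp::export(rng = false)]]
double cpp_state_V_dot(IntegerVector bA, IntegerVector bB, NumericVector bc,
                       IntegerVector kA, IntegerVector kB, NumericVector kc,
                       NumericVector vt, int mA, int mB) {
  const double* v = vt.begin();
  double tot = 0;
  std::vector<int> pA, qA, sA, pB, qB, sB;
  for (int i = 0; i < bA.size(); ++i) {
    for (int j = 0; j < kA.size(); ++j) {
      if (!t1_sparse((uint32_t)bA[i], (uint32_t)kA[j], pA, qA, sA)) continue;
      if (pA.empty()) continue;
      if (!t1_sparse((uint32_t)bB[i], (uint32_t)kB[j], pB, qB, sB)) continue;
      if (pB.empty()) continue;
      double acc = 0;
      for (size_t a = 0; a < pA.size(); ++a)
        for (size_t b = 0; b < pB.size(); ++b)
          acc += sA[a] * sB[b] *
            v[(size_t)pA[a] + (size_t)mA * qA[a] + (size_t)mA * mA * pB[b] +
              (size_t)mA * mA * mB * qB[b]];
      tot += bc[i] * kc[j] * acc;
    }
  }
  return tot;
}
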