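#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Bases are encoded A=0, C=1, G=2, T=3 so that Watson-Crick partners sum to 3.
// Stack parameters are indexed by the top-strand dinucleotide (5'->3'):
// index = 4 * first + second; the bottom strand is assumed complementary.

static const double INF = std::numeric_limits<double>::infinity();
static const double T37 = 310.15; // K, reference for loop dG tables

// Loop penalties are tabulated as dG37 by loop size and treated as purely
// entropic (dH = 0), so dG(T) = -T * dS with dS = -1000 * dG37 / 310.15.
// Sizes beyond the table are extrapolated with the Jacobson-Stockmayer term.
static inline double loop_dg37(const NumericVector &tab, int n) {
  int L = tab.size();
  if (n < 1) return 0.0;
  if (n <= L) return tab[n - 1];
  return tab[L - 1] + 2.44 * 1.9872e-3 * T37 * std::log((double)n / (double)L);
}

static inline double loop_ds(const NumericVector &tab, int n) {
  return -1000.0 * loop_dg37(tab, n) / T37;
}

// Minimum-free-energy intermolecular duplex between strand a (5'->3') and
// strand b (5'->3', antiparallel) at tempK.  Only Watson-Crick pairs, stacks,
// bulges and internal loops; no intramolecular structure, no multiloops.
// initDH/initDS are length-4 vectors giving the per-end initiation terms by
// the top-strand terminal base (A,C,G,T ordering), i.e. the terminal A.T or
// G.C duplex-initiation penalty.
// [[Rcpp::export]]
List duplex_mfe_cpp(IntegerVector a, IntegerVector b,
                    NumericVector stackDH, NumericVector stackDS,
                    NumericVector bulgeDG37, NumericVector intlDG37,
                    NumericVector initDH, NumericVector initDS,
                    double tempK, int maxLoop) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // reverse b so that the duplex is traversed left to right on both strands
  std::vector<int> br(m);
  for (int k = 0; k < m; ++k) br[k] = b[m - 1 - k];

  std::vector<double> H(n * m, 0.0), S(n * m, 0.0), G(n * m, INF);
  std::vector<int> prev(n * m, -1);

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      if (a[i] + br[k] != 3) continue;
      int idx = i * m + k;
      // open the duplex at this pair: one terminal initiation
      double bh = initDH[a[i]], bs = initDS[a[i]];
      double bg = bh - tempK * bs / 1000.0;
      int bp = -1;
      int gimax = std::min(i - 1, maxLoop);
      int gkmax = std::min(k - 1, maxLoop);
      for (int gi = 0; gi <= gimax; ++gi) {
        for (int gk = 0; gk <= gkmax; ++gk) {
          int pi = i - 1 - gi, pk = k - 1 - gk;
          int pidx = pi * m + pk;
          if (!std::isfinite(G[pidx])) continue;
          double dh, ds;
          if (gi == 0 && gk == 0) {
            int key = 4 * a[pi] + a[i];
            dh = stackDH[key];
            ds = stackDS[key];
          } else if (gi == 0 || gk == 0) {
            dh = 0.0;
            ds = loop_ds(bulgeDG37, gi + gk);
          } else {
            dh = 0.0;
            ds = loop_ds(intlDG37, gi + gk);
          }
          double g = G[pidx] + dh - tempK * ds / 1000.0;
          if (g < bg) {
            bg = g;
            bh = H[pidx] + dh;
            bs = S[pidx] + ds;
            bp = pidx;
          }
        }
      }
      H[idx] = bh; S[idx] = bs; G[idx] = bg; prev[idx] = bp;
    }
  }

  // close the duplex: second terminal initiation at the last pair
  double bestG = INF, bestH = 0.0, bestS = 0.0;
  int bestIdx = -1;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      int idx = i * m + k;
      if (!std::isfinite(G[idx])) continue;
      double g = G[idx] + initDH[a[i]] - tempK * initDS[a[i]] / 1000.0;
      if (g < bestG) {
        bestG = g;
        bestH = H[idx] + initDH[a[i]];
        bestS = S[idx] + initDS[a[i]];
        bestIdx = idx;
      }
    }
  }

  if (bestIdx < 0) {
    return List::create(_["found"] = false, _["dH"] = NA_REAL,
                        _["dS"] = NA_REAL, _["dG"] = NA_REAL,
                        _["npairs"] = 0, _["pairs"] = IntegerMatrix(0, 2));
  }

  // backtrack the pairing (1-based positions, b in its original orientation)
  std::vector<int> pi_list, pj_list;
  for (int idx = bestIdx; idx >= 0; idx = prev[idx]) {
    int i = idx / m, k = idx % m;
    pi_list.push_back(i + 1);
    pj_list.push_back(m - k); // m - 1 - k in 0-based -> 1-based
  }
  int np = pi_list.size();
  IntegerMatrix pairs(np, 2);
  for (int r = 0; r < np; ++r) {
    pairs(r, 0) = pi_list[np - 1 - r];
    pairs(r, 1) = pj_list[np - 1 - r];
  }
  return List::create(_["found"] = true, _["dH"] = bestH, _["dS"] = bestS,
                      _["dG"] = bestG, _["npairs"] = np, _["pairs"] = pairs);
}

// Minimum-free-energy hairpin fold of a single strand at tempK.  Stems are
// Watson-Crick stacks with bulges/internal loops; the closing loop must hold
// at least minLoop unpaired bases.  No multiloops, no initiation terms.
// [[Rcpp::export]]
List hairpin_mfe_cpp(IntegerVector a,
                     NumericVector stackDH, NumericVector stackDS,
                     NumericVector hairpinDG37, NumericVector bulgeDG37,
                     NumericVector intlDG37, double tempK, int maxLoop,
                     int minLoop) {
  int n = a.size();
  std::vector<double> H(n * n, 0.0), S(n * n, 0.0), G(n * n, INF);
  bool any = false;
  for (int span = minLoop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (a[i] + a[j] != 3) continue;
      int idx = i * n + j;
      // closing hairpin loop of size j - i - 1 (>= minLoop by construction)
      double ls = loop_ds(hairpinDG37, j - i - 1);
      double bh = 0.0, bs = ls, bg = -tempK * ls / 1000.0;
      int gimax = std::min(maxLoop, span - 2);
      for (int gi = 0; gi <= gimax; ++gi) {
        for (int gj = 0; gj <= gimax; ++gj) {
          int ip = i + 1 + gi, jp = j - 1 - gj;
          if (ip >= jp) continue;
          int pidx = ip * n + jp;
          if (!std::isfinite(G[pidx])) continue;
          double dh, ds;
          if (gi == 0 && gj == 0) {
            int key = 4 * a[i] + a[ip];
            dh = stackDH[key];
            ds = stackDS[key];
          } else if (gi == 0 || gj == 0) {
            dh = 0.0;
            ds = loop_ds(bulgeDG37, gi + gj);
          } else {
            dh = 0.0;
            ds = loop_ds(intlDG37, gi + gj);
          }
          double g = G[pidx] + dh - tempK * ds / 1000.0;
          if (g < bg) {
            bg = g;
            bh = H[pidx] + dh;
            bs = S[pidx] + ds;
          }
        }
      }
      H[idx] = bh; S[idx] = bs; G[idx] = bg;
      any = true;
    }
  }
  if (!any) {
    return List::create(_["found"] = false, _["dG"] = 0.0, _["dH"] = 0.0,
                        _["dS"] = 0.0);
  }
  double bestG = INF, bestH = 0.0, bestS = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + minLoop + 1; j < n; ++j) {
      int idx = i * n + j;
      if (std::isfinite(G[idx]) && G[idx] < bestG) {
        bestG = G[idx]; bestH = H[idx]; bestS = S[idx];
      }
    }
  }
  return List::create(_["found"] = true, _["dG"] = bestG, _["dH"] = bestH,
                      _["dS"] = bestS);
}
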