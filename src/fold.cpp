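#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Nested-structure minimum-score dynamic program shared by the Nussinov,
// Zuker-style and MEA engines.
//
//   emat(i,j)  score contributed by pair (i,j); +Inf where pairing is
//              disallowed (non-canonical, loop too short, ...)
//   stack      bonus added when (i,j) and (i+1,j-1) are both paired;
//              must be <= 0 for the interior rule below to be exact
//   pe         per-position pseudoenergy, added once per paired nucleotide
//
// Recurrences (0-based, half-open handling via span length):
//   V(i,j) = emat(i,j) + pe[i] + pe[j] + min(W(i+1,j-1), V(i+1,j-1)+stack)
//   W(i,j) = min(W(i,j-1), min_k V(k,j) + W(i,k-1))
//
// Tie-breaking is frozen at fill time: the pairing branch wins ties, and
// among pairing branches the smallest k wins. Traceback replays stored
// decisions, so no floating-point equality is ever tested twice.

static inline double get2(const std::vector<double>& m, int n, int i, int j) {
  // value of an empty interval is 0
  if (j < i) return 0.0;
  return m[(size_t)i * n + j];
}

// [[Rcpp::export]]
List cpp_mfe_fold(NumericMatrix emat, double stack, int min_loop,
                  NumericVector pe) {
  const int n = emat.nrow();
  if (emat.ncol() != n) stop("emat must be square");
  if ((int)pe.size() != n) stop("pe length must match emat");

  std::vector<double> V((size_t)n * n, R_PosInf), W((size_t)n * n, 0.0);
  // choiceW: -1 -> j unpaired, k>=0 -> pair (k,j); choiceV: 1 -> stacked
  std::vector<int> choiceW((size_t)n * n, -1), choiceV((size_t)n * n, 0);

  for (int span = min_loop + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      const int j = i + span - 1;
      // V(i,j)
      if (R_finite(emat(i, j))) {
        double interior = get2(W, n, i + 1, j - 1);
        int cv = 0;
        if (j - 1 >= i + 1) {
          double vin = V[(size_t)(i + 1) * n + (j - 1)];
          if (R_finite(vin) && vin + stack <= interior) {
            interior = vin + stack;
            cv = 1;
          }
        }
        V[(size_t)i * n + j] = emat(i, j) + pe[i] + pe[j] + interior;
        choiceV[(size_t)i * n + j] = cv;
      }
      // W(i,j)
      double best = get2(W, n, i, j - 1);
      int cw = -1;
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double vkj = V[(size_t)k * n + j];
        if (!R_finite(vkj)) continue;
        double cand = vkj + get2(W, n, i, k - 1);
        // pairing branch wins ties; first (smallest) k wins among pairs
        if (cand < best || (cand <= best && cw == -1)) {
          best = cand;
          cw = k;
        }
      }
      W[(size_t)i * n + j] = best;
      choiceW[(size_t)i * n + j] = cw;
    }
  }

  // traceback
  std::vector<int> pi, pj;
  std::vector<std::array<int, 3>> todo;  // (i, j, inV)
  if (n >= min_loop + 2) todo.push_back({0, n - 1, 0});
  while (!todo.empty()) {
    auto t = todo.back();
    todo.pop_back();
    int i = t[0], j = t[1];
    if (j - i + 1 < min_loop + 2) continue;
    if (t[2]) {  // in V(i,j): (i,j) is a pair
      pi.push_back(i);
      pj.push_back(j);
      if (choiceV[(size_t)i * n + j])
        todo.push_back({i + 1, j - 1, 1});
      else
        todo.push_back({i + 1, j - 1, 0});
    } else {  // in W(i,j)
      int k = choiceW[(size_t)i * n + j];
      if (k < 0) {
        todo.push_back({i, j - 1, 0});
      } else {
        todo.push_back({k, j, 1});
        if (k - 1 >= i) todo.push_back({i, k - 1, 0});
      }
    }
  }

  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  double score = (n >= min_loop + 2) ? W[(size_t)0 * n + (n - 1)] : 0.0;
  return List::create(_["pairs"] = pairs, _["score"] = score);
}

// McCaskill-style inside-outside over a pair-only Boltzmann ensemble.
// wmat(i,j) = exp(-E(i,j)/RT) for allowed pairs, 0 elsewhere. Per-nucleotide
// rescaling (factor 1/s per position) keeps the recursions finite for long
// sequences; the scale cancels exactly in the probability ratio.
// Outside recursion decomposes each exterior configuration by the immediate
// enclosing pair (p,q), O(n^4) overall — fine at the sequence lengths the
// MEA engine is used for.
// [[Rcpp::export]]
NumericMatrix cpp_pair_probs(NumericMatrix wmat, int min_loop) {
  const int n = wmat.nrow();
  if (wmat.ncol() != n) stop("wmat must be square");
  NumericMatrix P(n, n);
  if (n < min_loop + 2) return P;

  double wmax = 1.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (wmat(i, j) > wmax) wmax = wmat(i, j);
  const double s = std::sqrt(wmax);  // per-nucleotide scale
  const double u = 1.0 / s;

  auto wsc = [&](int i, int j) { return wmat(i, j) / (s * s); };

  std::vector<double> Q((size_t)n * n, 0.0), Qb((size_t)n * n, 0.0);
  // Q over empty interval = 1; single positions:
  auto q = [&](int i, int j) -> double {
    if (j < i) return 1.0;
    return Q[(size_t)i * n + j];
  };
  for (int i = 0; i < n; ++i) Q[(size_t)i * n + i] = u;
  for (int span = 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      const int j = i + span - 1;
      double acc = u * q(i, j - 1);
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double w = wsc(k, j);
        if (w <= 0.0) continue;
        double qb = w * q(k + 1, j - 1);
        Qb[(size_t)k * n + j] = qb;
        acc += q(i, k - 1) * qb;
      }
      Q[(size_t)i * n + j] = acc;
    }
  }
  const double Qtot = q(0, n - 1);
  if (!R_finite(Qtot) || Qtot <= 0.0)
    stop("partition function overflowed or vanished");

  // outside, by decreasing span
  std::vector<double> Qout((size_t)n * n, 0.0);
  for (int span = n; span >= min_loop + 2; --span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      const int j = i + span - 1;
      if (Qb[(size_t)i * n + j] <= 0.0) continue;
      double acc = q(0, i - 1) * q(j + 1, n - 1);
      for (int p = 0; p < i; ++p) {
        for (int qq = j + 1; qq < n; ++qq) {
          double w = wsc(p, qq);
          if (w <= 0.0) continue;
          double qo = Qout[(size_t)p * n + qq];
          if (qo <= 0.0) continue;
          acc += w * qo * q(p + 1, i - 1) * q(j + 1, qq - 1);
        }
      }
      Qout[(size_t)i * n + j] = acc;
      double prob = Qb[(size_t)i * n + j] * acc / Qtot;
      if (!R_finite(prob)) stop("pair probability overflowed");
      P(i, j) = prob;
    }
  }
  return P;
}
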