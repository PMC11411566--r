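#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Simplified Zuker-style minimum-free-energy folding.
//
// Interval DP with three tables:
//   V(i,j)  best energy of [i..j] given that (i,j) is a base pair
//   WM(i,j) best energy of [i..j] as a multiloop segment holding >= 1 branch
//           (each branch is charged the per-branch multiloop term)
//   W(j)    best energy of the prefix [0..j] (external bases are free)
// Loop decomposition per closing pair: stacking / bulge / interior / hairpin /
// multiloop with >= 2 enclosed branches. Energies come from the EnergyModel
// passed in as a flat list; interior+bulge spans are capped at maxInterior
// unpaired nucleotides (stacking is never capped).

static const double INF = 1e9;
static const double EPS = 1e-7;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
  }
  return -1;
}

// pair types: AU UA CG GC GU UG -> 0..5, -1 if unpairable
static inline int pairType(int a, int b, bool allowGU) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (allowGU && a == 2 && b == 3) return 4;
  if (allowGU && a == 3 && b == 2) return 5;
  return -1;
}

struct FoldCtx {
  int n;
  std::vector<int> s;
  std::vector<double> V, WM;
  std::vector<double> W;
  NumericMatrix stacking;
  double hairpinPenalty, bulgeBase, bulgeSlope, interiorBase, interiorSlope;
  double multiBase, multiBranch;
  int minHairpin, maxInterior;
  bool allowGU;
  std::string db;

  double& v(int i, int j) { return V[i * n + j]; }
  double& wm(int i, int j) { return WM[i * n + j]; }

  double twoLoopCost(int i, int j, int k, int l) {
    int g1 = k - i - 1, g2 = j - l - 1;
    if (g1 == 0 && g2 == 0) {
      int pt = pairType(s[i], s[j], allowGU);
      int qt = pairType(s[k], s[l], allowGU);
      return stacking(pt, qt);
    }
    int sz = g1 + g2;
    if (sz > maxInterior) return INF;
    if (g1 == 0 || g2 == 0) return bulgeBase + bulgeSlope * sz;
    return interiorBase + interiorSlope * sz;
  }

  void fill() {
    V.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    // pair-type lookup, computed once
    std::vector<signed char> P((size_t)n * n, -1);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        P[(size_t)i * n + j] = (signed char)pairType(s[i], s[j], allowGU);
    for (int span = minHairpin + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // --- V(i,j) ---
        int pt = P[(size_t)i * n + j];
        if (pt >= 0 && j - i - 1 >= minHairpin) {
          double best = hairpinPenalty;
          // stack (never capped)
          if (j - i - 2 > 0) {
            double inner = v(i + 1, j - 1);
            if (inner < INF) {
              int qt = P[(size_t)(i + 1) * n + (j - 1)];
              if (qt >= 0 && inner + stacking(pt, qt) < best)
                best = inner + stacking(pt, qt);
            }
          }
          // bulges: one side empty
          int gmax = std::min(maxInterior, j - i - 3);
          for (int g = 1; g <= gmax; ++g) {
            double pen = bulgeBase + bulgeSlope * g;
            double a = (j - 1 - (i + 1 + g) > 0) ? v(i + 1 + g, j - 1) : INF;
            if (a < INF && a + pen < best) best = a + pen;
            double b = (j - 1 - g - (i + 1) > 0) ? v(i + 1, j - 1 - g) : INF;
            if (b < INF && b + pen < best) best = b + pen;
          }
          // interior: both sides non-empty
          for (int g1 = 1; g1 <= maxInterior - 1; ++g1) {
            int k = i + 1 + g1;
            if (k >= j - 2) break;
            const double* Vk = &V[(size_t)k * n];
            int g2max = std::min(maxInterior - g1, j - k - 2);
            double base = interiorBase + interiorSlope * g1;
            for (int g2 = 1; g2 <= g2max; ++g2) {
              double a = Vk[j - 1 - g2];
              if (a < INF && a + base + interiorSlope * g2 < best)
                best = a + base + interiorSlope * g2;
            }
          }
          for (int m = i + 2; m <= j - 3; ++m) {
            double a = wm(i + 1, m), b = wm(m + 1, j - 1);
            if (a >= INF || b >= INF) continue;
            double cand = multiBase + a + b;
            if (cand < best) best = cand;
          }
          v(i, j) = best;
        }
        // --- WM(i,j) ---
        double wbest = INF;
        if (v(i, j) < INF) wbest = v(i, j) + multiBranch;
        if (i + 1 <= j && wm(i + 1, j) < wbest) wbest = wm(i + 1, j);
        if (i <= j - 1 && wm(i, j - 1) < wbest) wbest = wm(i, j - 1);
        for (int m = i + 1; m <= j - 1; ++m) {
          double a = wm(i, m), b = wm(m + 1, j);
          if (a >= INF || b >= INF) continue;
          if (a + b < wbest) wbest = a + b;
        }
        wm(i, j) = wbest;
      }
    }
    W.assign(n + 1, 0.0);
    for (int j = 0; j < n; ++j) {
      double best = W[j];
      for (int i = 0; i <= j; ++i) {
        if (v(i, j) < INF && W[i] + v(i, j) < best) best = W[i] + v(i, j);
      }
      W[j + 1] = best;
    }
  }

  void traceV(int i, int j);
  void traceWM(int i, int j);

  void traceW(int j) {
    while (j >= 0) {
      // leaving j unpaired wins ties deterministically
      if (std::fabs(W[j + 1] - W[j]) < EPS) { --j; continue; }
      int found = -1;
      for (int i = 0; i <= j; ++i) {
        if (v(i, j) < INF && std::fabs(W[i] + v(i, j) - W[j + 1]) < EPS) { found = i; break; }
      }
      if (found < 0) Rcpp::stop("fold traceback failed (external state)");
      traceV(found, j);
      j = found - 1;
    }
  }
};

void FoldCtx::traceV(int i, int j) {
  db[i] = '(';
  db[j] = ')';
  double e = v(i, j);
  if (std::fabs(e - hairpinPenalty) < EPS) {
    // hairpin is the first candidate checked; a two-loop of identical energy
    // would have been equally optimal — hairpin wins deterministically
    return;
  }
  int g1max = std::min(maxInterior, j - i - 2);
  for (int g1 = 0; g1 <= g1max; ++g1) {
    int k = i + 1 + g1;
    for (int g2 = 0; g2 <= maxInterior - g1; ++g2) {
      int l = j - 1 - g2;
      if (l <= k) break;
      if (v(k, l) >= INF) continue;
      double c = twoLoopCost(i, j, k, l);
      if (c < INF && std::fabs(v(k, l) + c - e) < EPS) { traceV(k, l); return; }
    }
  }
  for (int m = i + 2; m <= j - 3; ++m) {
    double a = wm(i + 1, m), b = wm(m + 1, j - 1);
    if (a >= INF || b >= INF) continue;
    if (std::fabs(multiBase + a + b - e) < EPS) {
      traceWM(i + 1, m);
      traceWM(m + 1, j - 1);
      return;
    }
  }
  Rcpp::stop("fold traceback failed (pair state)");
}

void FoldCtx::traceWM(int i, int j) {
  double e = wm(i, j);
  if (v(i, j) < INF && std::fabs(v(i, j) + multiBranch - e) < EPS) { traceV(i, j); return; }
  if (i + 1 <= j && std::fabs(wm(i + 1, j) - e) < EPS) { traceWM(i + 1, j); return; }
  if (i <= j - 1 && std::fabs(wm(i, j - 1) - e) < EPS) { traceWM(i, j - 1); return; }
  for (int m = i + 1; m <= j - 1; ++m) {
    double a = wm(i, m), b = wm(m + 1, j);
    if (a >= INF || b >= INF) continue;
    if (std::fabs(a + b - e) < EPS) { traceWM(i, m); traceWM(m + 1, j); return; }
  }
  Rcpp::stop("fold traceback failed (multiloop state)");
}

// [[Rcpp::export]]
List foldMfeCpp(std::string seq, NumericMatrix stacking, double hairpinPenalty,
                double bulgeBase, double bulgeSlope, double interiorBase,
                double interiorSlope, double multiBase, double multiBranch,
                int minHairpin, int maxInterior, bool allowGU) {
  FoldCtx ctx;
  ctx.n = (int)seq.size();
  ctx.s.resize(ctx.n);
  for (int i = 0; i < ctx.n; ++i) {
    int c = baseCode(seq[i]);
    if (c < 0) stop("fold: invalid residue '%c' (sequence must be over A/C/G/U)", seq[i]);
    ctx.s[i] = c;
  }
  ctx.stacking = stacking;
  ctx.hairpinPenalty = hairpinPenalty;
  ctx.bulgeBase = bulgeBase;
  ctx.bulgeSlope = bulgeSlope;
  ctx.interiorBase = interiorBase;
  ctx.interiorSlope = interiorSlope;
  ctx.multiBase = multiBase;
  ctx.multiBranch = multiBranch;
  ctx.minHairpin = minHairpin;
  ctx.maxInterior = maxInterior;
  ctx.allowGU = allowGU;
  ctx.db.assign(ctx.n, '.');
  if (ctx.n >= ctx.minHairpin + 2) {
    ctx.fill();
    ctx.traceW(ctx.n - 1);
    return List::create(_["mfe"] = ctx.W[ctx.n], _["structure"] = ctx.db);
  }
  return List::create(_["mfe"] = 0.0, _["structure"] = ctx.db);
}
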