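// Min-sum (max-product) loopy belief propagation over the radial CRF, with
// the sequential propagation schedule, message normalization, beam
// constraints and per-frame exact ring decoding; plus a pruned exhaustive
// enumerator used as a test oracle on tiny instances.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double BIG = 1e15;

namespace {

struct Model {
  int N, M, T;
  const double *D;            // N x M x T log-polar intensities
  const double *edge[2];      // unweighted edge cost maps, inner/outer
  // theta order: per kind {edge, spatial, temporal, systole, intTemporal,
  // intSpatial} for inner then outer, then crossRatio, wallVariance
  double th[14];
  int tES, epsRho, beamT, beamS, minWall;
  bool literalVar;
  const double *crossCost;    // length M: -log pmf (already includes floor)
  double thCross, thWV;
  std::vector<double> s1, s2; // prefix sums of D rows for wall variance

  inline double d(int n, int rho, int t) const {
    return D[n + (size_t)N * (rho + (size_t)M * t)];
  }
  inline int clampBin(int rho) const {
    return rho < 0 ? 0 : (rho > M - 1 ? M - 1 : rho);
  }
  inline double unary(int k, int n, int rho, int t) const {
    return th[k * 6 + 0] * edge[k][n + (size_t)N * (rho + (size_t)M * t)];
  }
  // factor between angles (n-1+N)%N and n within frame t; row n samples
  inline double spatialPair(int k, int t, int n, int rhoN, int rhoNm1) const {
    if (std::abs(rhoN - rhoNm1) > beamS) return BIG;
    int off = (k == 1) ? -epsRho : epsRho;  // outer inside, inner outside
    double dr = double(rhoN - rhoNm1) / M;
    return th[k * 6 + 1] * dr * dr +
           th[k * 6 + 5] * std::fabs(d(n, clampBin(rhoN + off), t) -
                                     d(n, clampBin(rhoNm1 + off), t));
  }
  // factor between (n, t-1) and (n, t); t is the 0-based current frame
  inline double temporalPair(int k, int t, int n, int rhoT, int rhoPrev) const {
    if (std::abs(rhoT - rhoPrev) > beamT) return BIG;
    int off = (k == 1) ? -epsRho : epsRho;
    double dr = double(rhoT - rhoPrev) / M;
    double sys = (t < tES) ? (rhoPrev < rhoT ? 1.0 : 0.0)
                           : (rhoT < rhoPrev ? 1.0 : 0.0);
    return th[k * 6 + 2] * dr * dr + th[k * 6 + 3] * sys +
           th[k * 6 + 4] * std::fabs(d(n, clampBin(rhoT + off), t) -
                                     d(n, clampBin(rhoPrev + off), t - 1));
  }
  void buildPrefix() {
    s1.assign((size_t)N * (M + 1) * T, 0.0);
    s2.assign((size_t)N * (M + 1) * T, 0.0);
    for (int t = 0; t < T; ++t)
      for (int n = 0; n < N; ++n) {
        size_t base = (size_t)(n + (size_t)N * (size_t)(M + 1) * t);
        double a1 = 0, a2 = 0;
        for (int r = 0; r < M; ++r) {
          double v = d(n, r, t);
          a1 += v; a2 += v * v;
          s1[base + (size_t)N * (r + 1)] = a1;
          s2[base + (size_t)N * (r + 1)] = a2;
        }
      }
  }
  inline double wallVar(int n, int t, int ri, int ro) const {
    int W = ro - ri;
    if (W <= 0) return 0.0;
    size_t base = (size_t)(n + (size_t)N * (size_t)(M + 1) * t);
    double S1 = s1[base + (size_t)N * (ro + 1)] - s1[base + (size_t)N * ri];
    double S2 = s2[base + (size_t)N * (ro + 1)] - s2[base + (size_t)N * ri];
    double den = literalVar ? W : (W + 1);
    double mu = S1 / den;
    int cnt = W + 1;
    return (S2 - 2.0 * mu * S1 + cnt * mu * mu) / den;
  }
  inline double crossPair(int t, int n, int ri, int ro) const {
    if (ro - ri < minWall) return BIG;
    double c = thCross * crossCost[ro - ri];
    if (thWV > 0) c += thWV * wallVar(n, t, ri, ro);
    return c;
  }
};

// message store for one contour: five incoming message families per node
struct Messages {
  int N, M, T;
  // index: rho + M*(n + N*t)
  std::vector<double> sF, sB, tF, tB, cx;
  Messages(int N_, int M_, int T_) : N(N_), M(M_), T(T_) {
    size_t sz = (size_t)N * M * T;
    sF.assign(sz, 0.0); sB.assign(sz, 0.0); tF.assign(sz, 0.0);
    tB.assign(sz, 0.0); cx.assign(sz, 0.0);
  }
  inline size_t at(int n, int t) const { return (size_t)M * (n + (size_t)N * t); }
};

inline void normalize(double *m, int M) {
  double mn = m[0];
  for (int r = 1; r < M; ++r) if (m[r] < mn) mn = m[r];
  for (int r = 0; r < M; ++r) m[r] -= mn;
}

// belief at (n,t) minus one excluded incoming family
void baseExcept(const Model &mod, const Messages &msg, int k, int n, int t,
                const double *excl, std::vector<double> &out) {
  size_t a = msg.at(n, t);
  for (int r = 0; r < mod.M; ++r) {
    double v = mod.unary(k, n, r, t) + msg.sF[a + r] + msg.sB[a + r] +
               msg.tF[a + r] + msg.tB[a + r] + msg.cx[a + r];
    if (excl) v -= excl[r];
    out[r] = v;
  }
}

void sweepContour(const Model &mod, Messages &msg, int k) {
  int N = mod.N, M = mod.M, T = mod.T;
  std::vector<double> tmp(M), out(M);
  // angular forward then backward, frame by frame
  for (int t = 0; t < T; ++t) {
    for (int n = 0; n < N; ++n) {
      int b = (n + 1) % N;
      baseExcept(mod, msg, k, n, t, &msg.sB[msg.at(n, t)], tmp);
      for (int rb = 0; rb < M; ++rb) {
        double best = BIG * 2;
        int lo = std::max(0, rb - mod.beamS), hi = std::min(M - 1, rb + mod.beamS);
        for (int ra = lo; ra <= hi; ++ra) {
          double v = tmp[ra] + mod.spatialPair(k, t, b, rb, ra);
          if (v < best) best = v;
        }
        out[rb] = best;
      }
      normalize(out.data(), M);
      std::copy(out.begin(), out.end(), msg.sF.begin() + msg.at(b, t));
    }
    for (int n = N - 1; n >= 0; --n) {
      int b = (n - 1 + N) % N;
      baseExcept(mod, msg, k, n, t, &msg.sF[msg.at(n, t)], tmp);
      for (int rb = 0; rb < M; ++rb) {
        double best = BIG * 2;
        int lo = std::max(0, rb - mod.beamS), hi = std::min(M - 1, rb + mod.beamS);
        for (int ra = lo; ra <= hi; ++ra) {
          double v = tmp[ra] + mod.spatialPair(k, t, n, ra, rb);
          if (v < best) best = v;
        }
        out[rb] = best;
      }
      normalize(out.data(), M);
      std::copy(out.begin(), out.end(), msg.sB.begin() + msg.at(b, t));
    }
  }
  // temporal forward then backward, angle by angle
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t + 1 < T; ++t) {
      baseExcept(mod, msg, k, n, t, &msg.tB[msg.at(n, t)], tmp);
      for (int rb = 0; rb < M; ++rb) {
        double best = BIG * 2;
        int lo = std::max(0, rb - mod.beamT), hi = std::min(M - 1, rb + mod.beamT);
        for (int ra = lo; ra <= hi; ++ra) {
          double v = tmp[ra] + mod.temporalPair(k, t + 1, n, rb, ra);
          if (v < best) best = v;
        }
        out[rb] = best;
      }
      normalize(out.data(), M);
      std::copy(out.begin(), out.end(), msg.tF.begin() + msg.at(n, t + 1));
    }
    for (int t = T - 1; t >= 1; --t) {
      baseExcept(mod, msg, k, n, t, &msg.tF[msg.at(n, t)], tmp);
      for (int rb = 0; rb < M; ++rb) {
        double best = BIG * 2;
        int lo = std::max(0, rb - mod.beamT), hi = std::min(M - 1, rb + mod.beamT);
        for (int ra = lo; ra <= hi; ++ra) {
          double v = tmp[ra] + mod.temporalPair(k, t, n, ra, rb);
          if (v < best) best = v;
        }
        out[rb] = best;
      }
      normalize(out.data(), M);
      std::copy(out.begin(), out.end(), msg.tB.begin() + msg.at(n, t - 1));
    }
  }
}

// cross messages: fromInner ? inner->outer : outer->inner, all nodes
void crossSweep(const Model &mod, Messages &from, Messages &to, bool fromInner) {
  int N = mod.N, M = mod.M, T = mod.T;
  int kFrom = fromInner ? 0 : 1;
  std::vector<double> tmp(M), out(M);
  for (int t = 0; t < T; ++t)
    for (int n = 0; n < N; ++n) {
      baseExcept(mod, from, kFrom, n, t, &from.cx[from.at(n, t)], tmp);
      for (int rb = 0; rb < M; ++rb) {
        double best = BIG * 2;
        if (fromInner) {           // rb is the outer bin
          for (int ri = 0; ri <= rb - mod.minWall; ++ri) {
            double v = tmp[ri] + mod.crossPair(t, n, ri, rb);
            if (v < best) best = v;
          }
        } else {                   // rb is the inner bin
          for (int ro = rb + mod.minWall; ro < M; ++ro) {
            double v = tmp[ro] + mod.crossPair(t, n, rb, ro);
            if (v < best) best = v;
          }
        }
        out[rb] = best;
      }
      normalize(out.data(), M);
      std::copy(out.begin(), out.end(), to.cx.begin() + to.at(n, t));
    }
}

// exact ring optimization of one frame's contour given node scores u (N x M)
// and a pairwise functor pair(n, rho_n, rho_{n-1}); conditions on the n=0
// bin, ties -> smallest bin. Returns bins via `sel`.
template <class PairF>
void solveRingG(const Model &mod, const std::vector<double> &u,
                std::vector<int> &sel, PairF pair) {
  int N = mod.N, M = mod.M, B = mod.beamS;
  std::vector<double> C(M), Cn(M);
  double bestTotal = std::numeric_limits<double>::infinity();
  int bestV = 0;
  for (int v = 0; v < M; ++v) {
    if (u[v] >= BIG) continue;
    // all node scores and pair costs are non-negative, so any candidate
    // whose own score already exceeds the incumbent cannot win
    if (u[v] >= bestTotal - 1e-12) continue;
    // chain DP over n = 1..N-1 with rho_0 = v
    for (int r = 0; r < M; ++r) C[r] = BIG * 4;
    C[v] = u[v];
    for (int n = 1; n < N; ++n) {
      for (int rb = 0; rb < M; ++rb) {
        double best = BIG * 4;
        int lo = std::max(0, rb - B), hi = std::min(M - 1, rb + B);
        for (int ra = lo; ra <= hi; ++ra) {
          double x = C[ra] + pair(n, rb, ra);
          if (x < best) best = x;
        }
        Cn[rb] = best + u[(size_t)n * M + rb];
      }
      std::swap(C, Cn);
    }
    double tot = std::numeric_limits<double>::infinity();
    for (int r = 0; r < M; ++r) {
      double x = C[r] + pair(0, v, r);  // seam (N-1, 0)
      if (x < tot) tot = x;
    }
    if (tot < bestTotal - 1e-12) { bestTotal = tot; bestV = v; }
  }
  // re-run the winning chain with backpointers
  std::vector<std::vector<int>> bp(N, std::vector<int>(M, -1));
  int v = bestV;
  for (int r = 0; r < M; ++r) C[r] = BIG * 4;
  C[v] = u[v];
  for (int n = 1; n < N; ++n) {
    for (int rb = 0; rb < M; ++rb) {
      double best = BIG * 4; int arg = -1;
      int lo = std::max(0, rb - B), hi = std::min(M - 1, rb + B);
      for (int ra = lo; ra <= hi; ++ra) {
        double x = C[ra] + pair(n, rb, ra);
        if (x < best - 1e-12) { best = x; arg = ra; }
      }
      Cn[rb] = best + u[(size_t)n * M + rb];
      bp[n][rb] = arg;
    }
    std::swap(C, Cn);
  }
  double tot = std::numeric_limits<double>::infinity(); int last = 0;
  for (int r = 0; r < M; ++r) {
    double x = C[r] + pair(0, v, r);
    if (x < tot - 1e-12) { tot = x; last = r; }
  }
  sel[N - 1] = last;
  for (int n = N - 1; n >= 1; --n) sel[n - 1] = bp[n][sel[n]];
  // sel[0] == v by construction
}


// tabulate a pairwise functor over the beam window: entry
// [(n*M + a)*(2B+1) + (b - a + B)] = f(n, a, b); the ring solver then
// reads costs instead of re-deriving them for every conditioning value
template <class F>
void buildPairTable(int N, int M, int B, std::vector<double> &tab, F f) {
  tab.assign((size_t)N * M * (2 * B + 1), 0.0);
  for (int n = 0; n < N; ++n)
    for (int a = 0; a < M; ++a) {
      int lo = std::max(0, a - B), hi = std::min(M - 1, a + B);
      for (int b = lo; b <= hi; ++b)
        tab[((size_t)n * M + a) * (2 * B + 1) + (b - a + B)] = f(n, a, b);
    }
}

template <class F>
void solveRingTab(const Model &mod, const std::vector<double> &u,
                  std::vector<int> &sel, std::vector<double> &tab, F f) {
  int B = mod.beamS, M = mod.M;
  buildPairTable(mod.N, M, B, tab, f);
  solveRingG(mod, u, sel, [&](int n, int a, int b) {
    if (std::abs(a - b) > B) return BIG;
    return tab[((size_t)n * M + a) * (2 * B + 1) + (b - a + B)];
  });
}

// plain single-contour ring solve with the model's spatial factor
void solveRing(const Model &mod, int k, int t,
               const std::vector<double> &u, std::vector<int> &sel,
               std::vector<double> &tab) {
  solveRingTab(mod, u, sel, tab, [&](int n, int a, int b) {
    return mod.spatialPair(k, t, n, a, b);
  });
}

// full model energy of a joint configuration (BIG-penalised when any beam
// or wall constraint is violated)
double totalEnergyC(const Model &mod, const IntegerMatrix &inner,
                    const IntegerMatrix &outer, bool both,
                    bool doInner = true, bool doOuter = true) {
  double E = 0;
  for (int k = 0; k < 2; ++k) {
    if ((k == 0 && !(both || doInner)) || (k == 1 && !(both || doOuter)))
      continue;
    const IntegerMatrix &b = (k == 0) ? inner : outer;
    for (int t = 0; t < mod.T; ++t)
      for (int n = 0; n < mod.N; ++n) {
        int nm1 = (n - 1 + mod.N) % mod.N;
        E += mod.unary(k, n, b(n, t), t) +
             mod.spatialPair(k, t, n, b(n, t), b(nm1, t));
        if (t > 0) E += mod.temporalPair(k, t, n, b(n, t), b(n, t - 1));
      }
  }
  if (both)
    for (int t = 0; t < mod.T; ++t)
      for (int n = 0; n < mod.N; ++n)
        E += mod.crossPair(t, n, inner(n, t), outer(n, t));
  return E;
}

} // namespace

// decode with one contour order (0: inner first) and refine with block
// coordinate descent; writes the configuration into inner/outer
void decodeAndRefine(const Model &mod, Messages &mIn, Messages &mOut,
                     bool both, bool doInner, bool doOuter, int order,
                     IntegerMatrix &inner, IntegerMatrix &outer) {
  std::vector<double> u((size_t)mod.N * mod.M), tab;
  std::vector<int> sel(mod.N);

  // decode one contour first (sequentially over frames), then the other
  // conditioned on the decided one through the actual cross factor so the
  // wall constraint holds exactly on every output
  for (int pass = 0; pass < 2; ++pass) {
    int k;
    if (!both) {
      if (pass == 1) break;
      k = doInner ? 0 : 1;
    } else {
      k = (order == 0) ? pass : 1 - pass;
    }
    Messages &msg = (k == 0) ? mIn : mOut;
    IntegerMatrix &res = (k == 0) ? inner : outer;
    IntegerMatrix &other = (k == 0) ? outer : inner;
    for (int t = 0; t < mod.T; ++t) {
      for (int n = 0; n < mod.N; ++n) {
        size_t a = msg.at(n, t);
        for (int r = 0; r < mod.M; ++r) {
          double v = mod.unary(k, n, r, t);
          if (t > 0) v += mod.temporalPair(k, t, n, r, res(n, t - 1));
          if (t + 1 < mod.T) v += msg.tB[a + r];
          if (both) {
            if (pass == 0) {
              v += msg.cx[a + r];
              // keep room for a feasible partner contour
              if (k == 0 && r + mod.minWall > mod.M - 1) v += BIG;
              if (k == 1 && r - mod.minWall < 0) v += BIG;
            } else {
              v += (k == 1) ? mod.crossPair(t, n, other(n, t), r)
                            : mod.crossPair(t, n, r, other(n, t));
            }
          }
          u[(size_t)n * mod.M + r] = v;
        }
      }
      solveRing(mod, k, t, u, sel, tab);
      for (int n = 0; n < mod.N; ++n) res(n, t) = sel[n];
    }
  }
  // backtracking refinement: block coordinate descent over frame-contour
  // rings, each block re-solved exactly conditioned on its decided
  // neighbours; the true energy is non-increasing, so this only sharpens
  // the decoded configuration (loopy beliefs are approximate)
  int active0 = doInner ? 0 : 1, active1 = doOuter ? 1 : 0;
  for (int sweep = 0; sweep < 20; ++sweep) {
    bool changed = false;
    for (int t = 0; t < mod.T; ++t)
      for (int k = active0; k <= active1; ++k) {
        IntegerMatrix &res = (k == 0) ? inner : outer;
        IntegerMatrix &other = (k == 0) ? outer : inner;
        for (int n = 0; n < mod.N; ++n)
          for (int r = 0; r < mod.M; ++r) {
            double v = mod.unary(k, n, r, t);
            if (t > 0) v += mod.temporalPair(k, t, n, r, res(n, t - 1));
            if (t + 1 < mod.T)
              v += mod.temporalPair(k, t + 1, n, res(n, t + 1), r);
            if (both)
              v += (k == 0) ? mod.crossPair(t, n, r, other(n, t))
                            : mod.crossPair(t, n, other(n, t), r);
            u[(size_t)n * mod.M + r] = v;
          }
        // cost of the current block under the conditional objective
        double cur = 0;
        for (int n = 0; n < mod.N; ++n) {
          cur += u[(size_t)n * mod.M + res(n, t)];
          int nm1 = (n - 1 + mod.N) % mod.N;
          cur += mod.spatialPair(k, t, n, res(n, t), res(nm1, t));
        }
        solveRing(mod, k, t, u, sel, tab);
        double opt = 0;
        for (int n = 0; n < mod.N; ++n) {
          opt += u[(size_t)n * mod.M + sel[n]];
          int nm1 = (n - 1 + mod.N) % mod.N;
          opt += mod.spatialPair(k, t, n, sel[n], sel[nm1]);
        }
        if (opt < cur - 1e-12) {
          for (int n = 0; n < mod.N; ++n) res(n, t) = sel[n];
          changed = true;
        }
      }
    // rigid-pair blocks: move one frame's inner and outer contours
    // together with their per-angle gap preserved, escaping traps where
    // the wall prior forbids moving either contour alone
    if (both)
      for (int t = 0; t < mod.T; ++t) {
        std::vector<int> gap(mod.N);
        for (int n = 0; n < mod.N; ++n) gap[n] = outer(n, t) - inner(n, t);
        for (int n = 0; n < mod.N; ++n)
          for (int r = 0; r < mod.M; ++r) {
            int ro = r + gap[n];
            double v;
            if (ro > mod.M - 1) v = BIG;
            else {
              v = mod.unary(0, n, r, t) + mod.unary(1, n, ro, t) +
                  mod.crossPair(t, n, r, ro);
              if (t > 0)
                v += mod.temporalPair(0, t, n, r, inner(n, t - 1)) +
                     mod.temporalPair(1, t, n, ro, outer(n, t - 1));
              if (t + 1 < mod.T)
                v += mod.temporalPair(0, t + 1, n, inner(n, t + 1), r) +
                     mod.temporalPair(1, t + 1, n, outer(n, t + 1), ro);
            }
            u[(size_t)n * mod.M + r] = v;
          }
        auto pairBoth = [&](int n, int a, int b) {
          int nm1 = (n - 1 + mod.N) % mod.N;
          int aro = a + gap[n], bro = b + gap[nm1];
          if (aro > mod.M - 1 || bro > mod.M - 1) return 2 * BIG;
          return mod.spatialPair(0, t, n, a, b) +
                 mod.spatialPair(1, t, n, aro, bro);
        };
        double cur = 0, opt = 0;
        for (int n = 0; n < mod.N; ++n) {
          int nm1 = (n - 1 + mod.N) % mod.N;
          cur += u[(size_t)n * mod.M + inner(n, t)] +
                 pairBoth(n, inner(n, t), inner(nm1, t));
        }
        solveRingTab(mod, u, sel, tab, pairBoth);
        for (int n = 0; n < mod.N; ++n) {
          int nm1 = (n - 1 + mod.N) % mod.N;
          opt += u[(size_t)n * mod.M + sel[n]] +
                 pairBoth(n, sel[n], sel[nm1]);
        }
        if (opt < cur - 1e-12) {
          for (int n = 0; n < mod.N; ++n) {
            inner(n, t) = sel[n];
            outer(n, t) = sel[n] + gap[n];
          }
          changed = true;
        }
      }
    // global rigid shift: the whole configuration moved by a constant
    // offset (coordinates frames that cannot improve one at a time)
    {
      double cur = totalEnergyC(mod, inner, outer, both, doInner, doOuter);
      int mnAll = mod.M, mxAll = 0;
      for (int t = 0; t < mod.T; ++t)
        for (int n = 0; n < mod.N; ++n) {
          if (both || doInner) {
            mnAll = std::min(mnAll, inner(n, t));
            mxAll = std::max(mxAll, inner(n, t));
          }
          if (both || doOuter) {
            mnAll = std::min(mnAll, outer(n, t));
            mxAll = std::max(mxAll, outer(n, t));
          }
        }
      int lo = -mnAll, hi = mod.M - 1 - mxAll;
      double best = cur; int bestD = 0;
      IntegerMatrix ti(mod.N, mod.T), to(mod.N, mod.T);
      for (int d = lo; d <= hi; ++d) {
        if (d == 0) continue;
        for (int t = 0; t < mod.T; ++t)
          for (int n = 0; n < mod.N; ++n) {
            ti(n, t) = inner(n, t) + d;
            to(n, t) = outer(n, t) + d;
          }
        double e = totalEnergyC(mod, ti, to, both, doInner, doOuter);
        if (e < best - 1e-12) { best = e; bestD = d; }
      }
      if (bestD != 0) {
        for (int t = 0; t < mod.T; ++t)
          for (int n = 0; n < mod.N; ++n) {
            inner(n, t) += bestD;
            outer(n, t) += bestD;
          }
        changed = true;
      }
    }
    if (!changed) break;
  }
}

// [[Rcpp::export(name = ".bp_segment")]]
List bp_segment(NumericVector D, IntegerVector dims,
                NumericVector edgeIn, NumericVector edgeOut,
                NumericVector theta, int tES, int epsRho,
                int beamT, int beamS, int minWall, bool literalVar,
                NumericVector crossCost, int nIter, int contours) {
  Model mod;
  mod.N = dims[0]; mod.M = dims[1]; mod.T = dims[2];
  mod.D = D.begin();
  mod.edge[0] = edgeIn.begin(); mod.edge[1] = edgeOut.begin();
  for (int i = 0; i < 14; ++i) mod.th[i] = theta[i];
  mod.tES = tES; mod.epsRho = epsRho; mod.beamT = beamT; mod.beamS = beamS;
  mod.minWall = minWall; mod.literalVar = literalVar;
  mod.crossCost = crossCost.begin();
  mod.thCross = theta[12]; mod.thWV = theta[13];
  mod.buildPrefix();

  bool both = contours == 0;
  bool doInner = both || contours == 1;
  bool doOuter = both || contours == 2;
  if (both && mod.minWall > mod.M - 1)
    stop("no state satisfies the minimum wall thickness; use a thinner-wall profile");

  Messages mIn(mod.N, mod.M, mod.T), mOut(mod.N, mod.M, mod.T);

  for (int it = 0; it < nIter; ++it) {
    if (both && it > 0) crossSweep(mod, mOut, mIn, false);
    if (doInner) sweepContour(mod, mIn, 0);
    if (both) crossSweep(mod, mIn, mOut, true);
    if (doOuter) sweepContour(mod, mOut, 1);
  }
  // refresh the outer-to-inner messages (the ones the next iteration would
  // start with) so the inner decode sees the final outer state
  if (both) crossSweep(mod, mOut, mIn, false);

  IntegerMatrix inner(mod.N, mod.T), outer(mod.N, mod.T);
  if (!both) {
    decodeAndRefine(mod, mIn, mOut, both, doInner, doOuter, 0, inner, outer);
  } else {
    // the two deterministic contour orders can disagree on loopy
    // instances; keep the lower-energy configuration
    IntegerMatrix i2(mod.N, mod.T), o2(mod.N, mod.T);
    decodeAndRefine(mod, mIn, mOut, both, doInner, doOuter, 0, inner, outer);
    decodeAndRefine(mod, mIn, mOut, both, doInner, doOuter, 1, i2, o2);
    double e1 = totalEnergyC(mod, inner, outer, both, doInner, doOuter);
    double e2 = totalEnergyC(mod, i2, o2, both, doInner, doOuter);
    if (e2 < e1 - 1e-12) { inner = i2; outer = o2; }
  }
  return List::create(_["inner"] = inner, _["outer"] = outer);
}

// [[Rcpp::export(name = ".brute_force")]]
List brute_force(IntegerVector dims, NumericVector unaryIn,
                 NumericVector unaryOut, NumericVector spIn,
                 NumericVector spOut, NumericVector tpIn, NumericVector tpOut,
                 NumericVector cross, bool both) {
  int N = dims[0], M = dims[1], T = dims[2];
  int K = both ? 2 : 1;
  int nv = K * N * T;
  // variable order: t, then n, then kind (inner before outer)
  std::vector<int> assign(nv, 0), best(nv, 0);
  double bestE = std::numeric_limits<double>::infinity();

  const double *un[2] = { unaryIn.begin(), unaryOut.begin() };
  const double *sp[2] = { spIn.begin(), spOut.begin() };
  const double *tp[2] = { tpIn.begin(), tpOut.begin() };
  const double *cr = cross.begin();
  // table layouts: unary [n + N*(rho + M*t)]
  // spatial  [a + M*(b + M*(n + N*t))] = factor(rho_n = a, rho_{n-1} = b), row n
  // temporal [a + M*(b + M*(n + N*t))] = factor(rho_t = a, rho_{t-1} = b)
  // cross    [ro + M*(ri + M*(n + N*t))]

  auto var = [&](int kind, int n, int t) { return K * (n + N * t) + kind; };

  // incremental cost of assigning variable v (kind, n, t) the value rho
  auto delta = [&](int idx, int rho) -> double {
    int kind = idx % K, rem = idx / K;
    int n = rem % N, t = rem / N;
    double e = un[kind][n + (size_t)N * (rho + (size_t)M * t)];
    if (n >= 1) {
      int prev = assign[var(kind, n - 1, t)];
      e += sp[kind][rho + (size_t)M * (prev + (size_t)M * (n + (size_t)N * t))];
    }
    if (n == N - 1 && N > 1) {  // seam factor (N-1, 0), row 0
      int r0 = assign[var(kind, 0, t)];
      e += sp[kind][r0 + (size_t)M * (rho + (size_t)M * (0 + (size_t)N * t))];
    }
    if (t >= 1) {
      int prev = assign[var(kind, n, t - 1)];
      e += tp[kind][rho + (size_t)M * (prev + (size_t)M * (n + (size_t)N * t))];
    }
    if (K == 2 && kind == 1) {
      int ri = assign[var(0, n, t)];
      e += cr[rho + (size_t)M * (ri + (size_t)M * (n + (size_t)N * t))];
    }
    return e;
  };

  std::vector<double> part(nv + 1, 0.0);
  int v = 0;
  std::vector<int> val(nv, -1);
  while (v >= 0) {
    ++val[v];
    if (val[v] >= M) { val[v] = -1; --v; continue; }
    assign[v] = val[v];
    double e = part[v] + delta(v, val[v]);
    if (e >= bestE) continue;          // prune (strict: first optimum kept)
    if (v == nv - 1) {
      bestE = e;
      best = assign;
      continue;
    }
    part[v + 1] = e;
    ++v;
  }

  IntegerMatrix inner(N, T), outer(N, T);
  for (int t = 0; t < T; ++t)
    for (int n = 0; n < N; ++n) {
      inner(n, t) = best[var(0, n, t)];
      if (K == 2) outer(n, t) = best[var(1, n, t)];
    }
  return List::create(_["inner"] = inner, _["outer"] = outer,
                      _["energy"] = bestE);
}
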