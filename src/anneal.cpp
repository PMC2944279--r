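// Simulated-annealing core for tableau matching.
//
// Tableau codes arrive as integers f*4+s with f,s in 0..3 (f: P,O,L,R;
// s: E,D,S,T); diagonals are -1. SSE types arrive as class integers
// (0 = strand, 1 = helix). Each restart runs on its own counter-based RNG
// stream derived from (seed, query id, entry id, restart index), so
// results are identical for any worker count or database order.

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() { state = mix64(state); return state; }
  // uniform on [0, 1)
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer on 0..n-1 (n small; modulo bias negligible and
  // irrelevant to correctness of the stochastic search)
  int unifInt(int n) { return (int)(next() % (uint64_t)n); }
};

static uint64_t fnv1a(const std::string &s, uint64_t h) {
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 0x100000001B3ULL;
  }
  return h;
}

static uint64_t pairSeed(int seed, const std::string &qid,
                         const std::string &did) {
  uint64_t h = 0xCBF29CE484222325ULL;
  h = fnv1a(qid, h);
  h ^= 0xFFULL; h *= 0x100000001B3ULL; // separator
  h = fnv1a(did, h);
  h ^= (uint64_t)(int64_t)seed;
  return mix64(h);
}

// zeta on integer codes: 2 identical, 1 one shared character, -2 otherwise
static inline int zetaInt(int a, int b) {
  if (a == b) return 2;
  return ((a >> 2) == (b >> 2) || (a & 3) == (b & 3)) ? 1 : -2;
}

struct Problem {
  int nA, nB;
  const int *codesA, *codesB;   // column-major nA*nA / nB*nB
  const int *clsA, *clsB;
  const double *dA, *dB;
  double tau;
  bool seq;

  inline int tA(int i, int k) const { return codesA[i + nA * k]; }
  inline int tB(int j, int l) const { return codesB[j + nB * l]; }
  inline double distA(int i, int k) const { return dA[i + nA * k]; }
  inline double distB(int j, int l) const { return dB[j + nB * l]; }
};

// Contribution of assigning query SSE i to database SSE j (1-based j;
// 0 = unmatched) given the other entries of v: both ordered pairs (i,k)
// and (k,i) are counted, hence the factor 2. O(nA).
static int contribution(const Problem &p, const std::vector<int> &v,
                        int i, int j) {
  if (j == 0) return 0;
  int s = 0;
  for (int k = 0; k < p.nA; ++k) {
    if (k == i || v[k] == 0) continue;
    int l = v[k];
    if (std::fabs(p.distA(i, k) - p.distB(j - 1, l - 1)) <= p.tau)
      s += zetaInt(p.tA(i, k), p.tB(j - 1, l - 1));
  }
  return 2 * s;
}

static int objectiveFull(const Problem &p, const std::vector<int> &v) {
  // summing per-SSE contributions counts every ordered pair twice
  int s = 0;
  for (int i = 0; i < p.nA; ++i)
    if (v[i] != 0) s += contribution(p, v, i, v[i]);
  return s / 2;
}

// candidate set for moving SSE i: type class, injectivity, optional
// ordering, current assignment excluded
static void candidates(const Problem &p, const std::vector<int> &v, int i,
                       std::vector<int> &out) {
  out.clear();
  int lo = 0, hi = p.nB + 1;
  if (p.seq) {
    for (int k = 0; k < i; ++k)
      if (v[k] != 0 && v[k] > lo) lo = v[k];
    for (int k = i + 1; k < p.nA; ++k)
      if (v[k] != 0 && v[k] < hi) hi = v[k];
  }
  for (int j = 1; j <= p.nB; ++j) {
    if (j == v[i]) continue;
    if (p.clsB[j - 1] != p.clsA[i]) continue;
    if (p.seq) {
      if (j <= lo || j >= hi) continue;
    } else {
      bool used = false;
      for (int k = 0; k < p.nA; ++k)
        if (k != i && v[k] == j) { used = true; break; }
      if (used) continue;
    }
    out.push_back(j);
  }
}

// initial state: scan i = 1..nA, with probability pm match to the lowest
// unused same-class j greater than the last assigned index
static void randomInit(const Problem &p, double pm, Rng &rng,
                       std::vector<int> &v) {
  v.assign(p.nA, 0);
  int last = 0;
  for (int i = 0; i < p.nA; ++i) {
    if (rng.u01() < pm) {
      for (int j = last + 1; j <= p.nB; ++j) {
        if (p.clsB[j - 1] == p.clsA[i]) { v[i] = j; last = j; break; }
      }
    }
  }
}

// one annealing run; returns best objective, best state in vbest
static int annealOnce(const Problem &p, double T0, double alpha, int iters,
                      double pm, Rng &rng, std::vector<int> &vbest) {
  std::vector<int> v;
  randomInit(p, pm, rng, v);
  int g = objectiveFull(p, v);
  vbest = v;
  int gbest = g;
  double T = T0;
  std::vector<int> J;
  J.reserve(p.nB);
  for (int it = 0; it < iters; ++it) {
    int i = rng.unifInt(p.nA);
    candidates(p, v, i, J);
    int jnew = J.empty() ? 0 : J[rng.unifInt((int)J.size())];
    int delta = contribution(p, v, i, jnew) - contribution(p, v, i, v[i]);
    int gnew = g + delta;
    double pdraw = rng.u01();
    bool accept = (gnew > gbest) || (std::exp((double)delta / T) > pdraw);
    if (accept) {
      v[i] = jnew;
      g = gnew;
      if (g > gbest) { gbest = g; vbest = v; }
    }
    T *= alpha;
  }
  return gbest;
}

static Problem makeProblem(const IntegerMatrix &codesA,
                           const IntegerVector &clsA,
                           const NumericMatrix &dA,
                           const IntegerMatrix &codesB,
                           const IntegerVector &clsB,
                           const NumericMatrix &dB,
                           double tau, bool seq) {
  Problem p;
  p.nA = codesA.nrow();
  p.nB = codesB.nrow();
  p.codesA = INTEGER(codesA);
  p.codesB = INTEGER(codesB);
  p.clsA = INTEGER(clsA);
  p.clsB = INTEGER(clsB);
  p.dA = REAL(dA);
  p.dB = REAL(dB);
  p.tau = tau;
  p.seq = seq;
  return p;
}

// [[Rcpp::export(name = ".cppSearchPair")]]
List cppSearchPair(IntegerMatrix codesA, IntegerVector clsA, NumericMatrix dA,
                   IntegerMatrix codesB, IntegerVector clsB, NumericMatrix dB,
                   double tau, bool sequential, double T0, double alpha,
                   int iters, double pm, int restarts, int restartFrom,
                   int seed, std::string queryId, std::string dbId) {
  Problem p = makeProblem(codesA, clsA, dA, codesB, clsB, dB, tau,
                          sequential);
  uint64_t base = pairSeed(seed, queryId, dbId);
  std::vector<int> vbest(p.nA, 0), vrun;
  int gbest = INT_MIN;
  for (int r = 0; r < restarts; ++r) {
    Rng rng(mix64(base ^ (uint64_t)(restartFrom + r)));
    int g = annealOnce(p, T0, alpha, iters, pm, rng, vrun);
    if (g > gbest) { gbest = g; vbest = vrun; }
  }
  return List::create(_["raw"] = gbest,
                      _["state"] = IntegerVector(vbest.begin(), vbest.end()));
}

// [[Rcpp::export(name = ".cppRandomInit")]]
IntegerVector cppRandomInit(IntegerVector clsA, IntegerVector clsB, double pm,
                            int seed, std::string queryId, std::string dbId,
                            int restartIndex) {
  Problem p;
  p.nA = clsA.size();
  p.nB = clsB.size();
  p.clsA = INTEGER(clsA);
  p.clsB = INTEGER(clsB);
  uint64_t base = pairSeed(seed, queryId, dbId);
  Rng rng(mix64(base ^ (uint64_t)restartIndex));
  std::vector<int> v;
  randomInit(p, pm, rng, v);
  return IntegerVector(v.begin(), v.end());
}
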