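// Exact stochastic simulation (Gillespie direct method) of the three-gene
// chromatin-modification reaction system.  The engine is generic over the
// channel table built in R: each channel's propensity is
//   rate * value(s1) * value(s2) * modifier(mod)
// with species codes 1..18 (state entries), 19..27 (per-gene repressive-mark
// sums) and modifier codes 0 none, 1 Hill(X_O/K_A), 2 X_T/denomT,
// 3 X_J/denomJ, 4..6 piecewise-constant overexpression inputs.
//
// Time-varying inputs are piecewise constant; a proposed jump that would
// cross a schedule breakpoint (or division time) is capped there and the
// exponential clock redrawn, which is exact for constant propensities
// between breakpoints.
//
// Each trajectory owns a counter-based RNG stream (xoshiro256++ seeded via
// splitmix64 from (base_seed, trajectory_index)), so runs are bit-identical
// for identical inputs and arms can share per-trajectory seeds.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0, 1], safe for log
  double unif_pos() { return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0); }
  double expo() { return -std::log(unif_pos()); }
  int binom(int n, double p) {
    int k = 0;
    for (int i = 0; i < n; ++i) if (unif() < p) ++k;
    return k;
  }
  bool bern(double p) { return unif() < p; }
};

inline double species_value(const double *state, int code) {
  if (code == 0) return 1.0;
  if (code <= 18) return state[code - 1];
  int g = (code - 19) % 3;          // gene index 0..2
  int fam = (code - 19) / 3;        // 0: R1+R2+R12, 1: R2+R12, 2: R1+R12
  const double *s = state + 5 * g;
  switch (fam) {
  case 0: return s[2] + s[3] + s[4];
  case 1: return s[3] + s[4];
  default: return s[2] + s[4];
  }
}

struct Engine {
  int M;
  const double *rate;
  const int *s1, *s2, *mod;
  double K_A, denomT, denomJ;
  const double *levels;  // 3 x K, column = schedule interval

  double prop(const double *state, int seg, int j) const {
    double a = rate[j] * species_value(state, s1[j]) *
               species_value(state, s2[j]);
    switch (mod[j]) {
    case 0: break;
    case 1: { double X = state[15]; a *= X / (K_A + X); break; }
    case 2: a *= state[16] / denomT; break;
    case 3: a *= state[17] / denomJ; break;
    default: a *= levels[3 * seg + (mod[j] - 4)]; break;
    }
    return a;
  }
};

} // namespace

// [[Rcpp::export]]
List ssa_run_cpp(NumericVector rate, IntegerVector s1, IntegerVector s2,
                 IntegerVector mod, IntegerMatrix update,
                 NumericVector sched_breaks, NumericMatrix sched_levels,
                 NumericVector init, NumericVector grid, double tau_end,
                 double K_A, double denomT, double denomJ,
                 int base_seed, int traj_index,
                 bool division, double division_period, double eta,
                 double max_events) {
  const int M = rate.size();
  if (update.nrow() != 18 || update.ncol() != M)
    stop("update matrix must be 18 x n_channels");
  double state[18];
  for (int i = 0; i < 18; ++i) state[i] = init[i];

  Engine eng{M, REAL(rate), INTEGER(s1), INTEGER(s2), INTEGER(mod),
             K_A, denomT, denomJ, REAL(sched_levels)};
  uint64_t key = (uint64_t)(uint32_t)base_seed << 32 |
                 (uint64_t)(uint32_t)traj_index;
  Xoshiro rng(key);

  const int G = grid.size();
  NumericMatrix out(G, 18);
  int gi = 0;
  auto record_until = [&](double tnew) {
    while (gi < G && grid[gi] < tnew) {
      for (int i = 0; i < 18; ++i) out(gi, i) = state[i];
      ++gi;
    }
  };

  // sparse update representation
  std::vector<int> u_n(M), u_idx(2 * M), u_val(2 * M);
  for (int j = 0; j < M; ++j) {
    int n = 0;
    for (int i = 0; i < 18; ++i) {
      int v = update(i, j);
      if (v != 0) { u_idx[2 * j + n] = i; u_val[2 * j + n] = v; ++n; }
    }
    u_n[j] = n;
  }

  const int K = sched_breaks.size();  // breakpoints incl. 0 and tau_end
  int seg = 0;
  double t = 0.0, next_div = division ? division_period : R_PosInf;
  double events = 0.0;
  std::vector<double> a(M);

  while (t < tau_end) {
    double sched_next = (seg + 1 < K) ? sched_breaks[seg + 1] : tau_end;
    double barrier = std::min(std::min(sched_next, next_div), tau_end);

    double a0 = 0.0;
    for (int j = 0; j < M; ++j) { a[j] = eng.prop(state, seg, j); a0 += a[j]; }

    bool fired = false;
    if (a0 > 0.0) {
      double dt = rng.expo() / a0;
      if (t + dt < barrier) {
        t += dt;
        record_until(t);
        double target = rng.unif() * a0, cum = 0.0;
        int j = M - 1;
        for (int k = 0; k < M; ++k) {
          cum += a[k];
          if (target < cum) { j = k; break; }
        }
        for (int k = 0; k < u_n[j]; ++k) state[u_idx[2 * j + k]] += u_val[2 * j + k];
        events += 1.0;
        fired = true;
        if (events > max_events) stop("event budget exceeded (max_events)");
      }
    }
    if (!fired) {
      t = barrier;
      record_until(t);
      if (division && t >= next_div - 1e-12 && t < tau_end) {
        // binomial partitioning at division
        for (int g = 0; g < 3; ++g) {
          double *s = state + 5 * g;
          int nA = (int)s[1], nR1 = (int)s[2], nR2 = (int)s[3],
              nR12 = (int)s[4];
          int keepA = rng.binom(nA, 0.5);
          s[1] = keepA; s[0] += nA - keepA;
          int keepR2 = rng.binom(nR2, 0.5);
          s[3] = keepR2; s[0] += nR2 - keepR2;
          int loseR1 = rng.binom(nR1, eta / 2.0);
          s[2] -= loseR1; s[0] += loseR1;
          for (int i = 0; i < nR12; ++i) {
            bool keepK = rng.bern(0.5);       // H3K9me3 retained
            bool keepM = !rng.bern(eta / 2.0); // CpGme survives
            s[4] -= 1;
            if (keepK && keepM) s[4] += 1;
            else if (!keepK && keepM) s[2] += 1;
            else if (keepK) s[3] += 1;
            else s[0] += 1;
          }
        }
        for (int i = 15; i < 18; ++i)
          state[i] = rng.binom((int)state[i], 0.5);
        next_div += division_period;
      }
      // advance to the schedule interval containing t (intervals 0..K-2)
      while (seg < K - 2 && sched_breaks[seg + 1] <= t + 1e-12) ++seg;
    }
  }
  record_until(R_PosInf);

  return List::create(_["states"] = out, _["event_count"] = events);
}

// [[Rcpp::export]]
NumericVector ssa_props_cpp(NumericVector rate, IntegerVector s1,
                            IntegerVector s2, IntegerVector mod,
                            NumericVector state, NumericVector u_now,
                            double K_A, double denomT, double denomJ) {
  const int M = rate.size();
  NumericVector out(M);
  NumericMatrix lev(3, 1);
  for (int i = 0; i < 3; ++i) lev(i, 0) = u_now[i];
  Engine eng{M, REAL(rate), INTEGER(s1), INTEGER(s2), INTEGER(mod),
             K_A, denomT, denomJ, REAL(lev)};
  double st[18];
  for (int i = 0; i < 18; ++i) st[i] = state[i];
  for (int j = 0; j < M; ++j) out[j] = eng.prop(st, 0, j);
  return out;
}
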