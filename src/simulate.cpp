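#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>

using namespace Rcpp;

// splitmix64: used both to condition the master seed and to derive
// independent per-cell streams by counter (cell index), so ensembles are
// reproducible regardless of execution order.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t cell_seed(uint64_t master, uint64_t index) {
  return splitmix64(splitmix64(master) ^ (0xA5A5A5A5A5A5A5A5ULL + index));
}

// uniform in (0, 1); built from raw 53-bit output so results are identical
// across standard libraries (std::uniform_real_distribution is not portable)
static inline double runif01(std::mt19937_64 &g) {
  return (static_cast<double>(g() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

struct SimResult {
  std::vector<double> times;
  std::vector<int> counts;
  int n_final;
  bool diverged;
  double t_stop;
};

// Exact stochastic simulation (Gillespie direct method): exponential waiting
// times from the four propensities, one event per firing.
static SimResult sim_event(double kdn, double kf, double g, double ku,
                           int n0, double t_end, double cap,
                           uint64_t seed, bool record) {
  std::mt19937_64 rng(seed);
  SimResult res;
  res.diverged = false;
  double t = 0.0;
  double n = n0;
  if (record) { res.times.push_back(0.0); res.counts.push_back(n0); }
  while (true) {
    double a1 = kdn;
    double a2 = kf * n;
    double a3 = g * n;
    double a4 = ku * n * (n - 1.0);
    double a0 = a1 + a2 + a3 + a4;
    if (a0 <= 0.0) { t = t_end; break; }  // absorbing state: nothing can fire
    double dt = -std::log(runif01(rng)) / a0;
    if (t + dt > t_end) { t = t_end; break; }
    t += dt;
    double u = runif01(rng) * a0;
    if (u < a1 + a2) n += 1.0; else n -= 1.0;
    if (record) { res.times.push_back(t); res.counts.push_back((int)n); }
    if (n > cap) { res.diverged = true; break; }
  }
  res.n_final = (int)n;
  res.t_stop = t;
  return res;
}

// Fixed-step scheme: per step a single uniform draw is compared against the
// cumulative first-order event probabilities of the four processes, so at
// most one event fires per step.
static SimResult sim_fixed(double kdn, double kf, double g, double ku,
                           int n0, double t_end, double dt, double cap,
                           uint64_t seed, bool record) {
  std::mt19937_64 rng(seed);
  SimResult res;
  res.diverged = false;
  double n = n0;
  if (record) { res.times.push_back(0.0); res.counts.push_back(n0); }
  long long nsteps = (long long)std::ceil(t_end / dt - 1e-9);
  double t = 0.0;
  for (long long s = 0; s < nsteps; ++s) {
    double p1 = kdn * dt;
    double p2 = kf * n * dt;
    double p3 = g * n * dt;
    double p4 = ku * n * (n - 1.0) * dt;
    double ptot = p1 + p2 + p3 + p4;
    if (ptot >= 1.0)
      stop("summed per-step event probability reached %.3g (>= 1) at n = %d; reduce dt", ptot, (int)n);
    double u = runif01(rng);
    int dn = 0;
    if (u < p1 + p2) dn = 1;
    else if (u < ptot) dn = -1;
    t = (s + 1) * dt;
    if (dn != 0) {
      n += dn;
      if (record) { res.times.push_back(t); res.counts.push_back((int)n); }
      if (n > cap) { res.diverged = true; break; }
    }
  }
  res.n_final = (int)n;
  res.t_stop = t;
  return res;
}

// [[Rcpp::export(name = ".sim_trajectory_cpp")]]
List sim_trajectory_cpp(double k_de_novo, double k_fission, double gamma_,
                        double k_fusion, int n0, double t_end, double dt,
                        bool fixed_step, double cap, double seed) {
  SimResult r;
  uint64_t s = (uint64_t)seed;
  if (fixed_step)
    r = sim_fixed(k_de_novo, k_fission, gamma_, k_fusion, n0, t_end, dt,
                  cap, s, true);
  else
    r = sim_event(k_de_novo, k_fission, gamma_, k_fusion, n0, t_end,
                  cap, s, true);
  return List::create(_["time"] = wrap(r.times),
                      _["count"] = wrap(r.counts),
                      _["diverged"] = r.diverged,
                      _["t_stop"] = r.t_stop);
}

// [[Rcpp::export(name = ".sim_ensemble_cpp")]]
List sim_ensemble_cpp(double k_de_novo, double k_fission, double gamma_,
                      double k_fusion, int n0, double tau, double dt,
                      bool fixed_step, double cap, double seed,
                      int n_cells) {
  IntegerVector final_counts(n_cells);
  bool any_diverged = false;
  uint64_t master = (uint64_t)seed;
  for (int i = 0; i < n_cells; ++i) {
    uint64_t s = cell_seed(master, (uint64_t)i);
    SimResult r;
    if (fixed_step)
      r = sim_fixed(k_de_novo, k_fission, gamma_, k_fusion, n0, tau, dt,
                    cap, s, false);
    else
      r = sim_event(k_de_novo, k_fission, gamma_, k_fusion, n0, tau,
                    cap, s, false);
    final_counts[i] = r.n_final;
    if (r.diverged) { any_diverged = true; break; }
  }
  return List::create(_["counts"] = final_counts,
                      _["diverged"] = any_diverged);
}
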