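// Asynchronous Monte Carlo engine for the three-state spin cascade.
//
// The coupling matrix W = S~ + S~^T is passed in compressed sparse column
// form; W must be symmetric with zero diagonal, so column i of W equals
// row i and the local field of node i is the dot product of column i with
// the current spin vector.

#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// mt19937_64 output is fully specified by the standard; the bounded draw
// uses rejection sampling because std::uniform_int_distribution is
// implementation-defined and would break bit-reproducibility guarantees.
struct SpinRng {
  std::mt19937_64 gen;
  explicit SpinRng(uint64_t seed) : gen(seed) {}
  uint64_t bounded(uint64_t n) {
    if (n <= 1) return 0;
    const uint64_t threshold = (-n) % n;  // 2^64 mod n
    for (;;) {
      uint64_t r = gen();
      if (r >= threshold) return r % n;
    }
  }
};

static inline void shuffle_in_place(std::vector<int>& v, SpinRng& rng) {
  const size_t m = v.size();
  for (size_t k = 0; k + 1 < m; ++k) {
    size_t j = k + (size_t)rng.bounded((uint64_t)(m - k));
    std::swap(v[k], v[j]);
  }
}

// One full asynchronous sweep along `order`; each new spin value is visible
// to subsequent updates. Returns the number of spins that changed and keeps
// the running count of red variable nodes up to date.
static int sweep_once(std::vector<int>& spin, const std::vector<int>& order,
                      const int* wp, const int* wi, const double* wx,
                      int& var_red) {
  int changed = 0;
  for (size_t idx = 0; idx < order.size(); ++idx) {
    const int i = order[idx];
    double z = 0.0;
    for (int k = wp[i]; k < wp[i + 1]; ++k) z += wx[k] * spin[wi[k]];
    if (z > 0.0) {
      if (spin[i] != 1) {
        ++changed;
        ++var_red;
        spin[i] = 1;
      }
    } else if (z < 0.0) {
      if (spin[i] != -1) {
        ++changed;
        if (spin[i] == 1) --var_red;
        spin[i] = -1;
      }
    }
    // z == 0: spin unchanged
  }
  return changed;
}

// [[Rcpp::export]]
List run_engine_cpp(IntegerVector wp, IntegerVector wi, NumericVector wx,
                    IntegerVector pinned, IntegerVector variable0,
                    IntegerVector candidate0, int n_ib, bool fixed_config,
                    IntegerVector config0, int init_sign, int tau_max, int R,
                    int seed, bool store_real, bool return_spins) {
  const int n = pinned.size();
  const int nv = variable0.size();
  const int nc = candidate0.size();
  if (tau_max < 1) stop("tau_max must be >= 1");
  if (R < 1) stop("R must be >= 1");
  if (!fixed_config && n_ib > nc)
    stop("n_ib exceeds the candidate set size");

  std::vector<int> spin(n);
  std::vector<int> order(variable0.begin(), variable0.end());
  std::vector<int> pool(nc);
  std::vector<int> blues(fixed_config ? config0.size() : n_ib);

  NumericVector red_count(n), blue_count(n);
  NumericVector traj(tau_max);
  NumericVector fr_real(R);
  IntegerVector tau_last(R);
  LogicalVector converged(R);
  IntegerMatrix blues_out(store_real ? (int)blues.size() : 0,
                          store_real ? R : 0);
  IntegerMatrix spins_out(return_spins ? n : 0, return_spins ? R : 0);

  const int* wpp = INTEGER(wp);
  const int* wip = INTEGER(wi);
  const double* wxp = REAL(wx);

  for (int r = 0; r < R; ++r) {
    const uint64_t stream =
        splitmix64(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)(r + 1));
    SpinRng rng(stream);

    for (int i = 0; i < n; ++i) spin[i] = pinned[i];

    if (fixed_config) {
      for (size_t k = 0; k < blues.size(); ++k) blues[k] = config0[k];
    } else {
      std::copy(candidate0.begin(), candidate0.end(), pool.begin());
      for (int k = 0; k < n_ib; ++k) {
        int j = k + (int)rng.bounded((uint64_t)(nc - k));
        std::swap(pool[k], pool[j]);
        blues[k] = pool[k];
      }
    }
    for (size_t k = 0; k < blues.size(); ++k) spin[blues[k]] = init_sign;

    int var_red = 0;
    for (int v = 0; v < nv; ++v) var_red += (spin[variable0[v]] == 1);

    int tl = tau_max;
    bool conv = false;
    for (int t = 1; t <= tau_max; ++t) {
      shuffle_in_place(order, rng);
      int changed = sweep_once(spin, order, wpp, wip, wxp, var_red);
      const double frv = nv > 0 ? (double)var_red / nv : 0.0;
      traj[t - 1] += frv;
      if (changed == 0) {
        tl = t;
        conv = true;
        // absorbing-state verification: a converged sweep must stay
        // converged under any later update order
        shuffle_in_place(order, rng);
        int again = sweep_once(spin, order, wpp, wip, wxp, var_red);
        if (again != 0)
          stop("absorbing-state violation: converged sweep changed a spin");
        for (int tt = t + 1; tt <= tau_max; ++tt) traj[tt - 1] += frv;
        break;
      }
    }
    tau_last[r] = tl;
    converged[r] = conv;
    fr_real[r] = nv > 0 ? (double)var_red / nv : 0.0;

    for (int i = 0; i < n; ++i) {
      if (spin[i] == 1) red_count[i] += 1.0;
      else if (spin[i] == -1) blue_count[i] += 1.0;
    }
    if (store_real)
      for (size_t k = 0; k < blues.size(); ++k) blues_out(k, r) = blues[k];
    if (return_spins)
      for (int i = 0; i < n; ++i) spins_out(i, r) = spin[i];
  }
  for (int t = 0; t < tau_max; ++t) traj[t] /= R;

  return List::create(
      _["red_count"] = red_count, _["blue_count"] = blue_count,
      _["tau_last"] = tau_last, _["converged"] = converged,
      _["fr_trajectory"] = traj, _["fr_real"] = fr_real,
      _["initial_blues"] = blues_out, _["final_spins"] = spins_out);
}
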