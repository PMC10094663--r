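#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Counter-based RNG: splitmix64 streams keyed by (master seed, substream id).
// Each walk repeat / each category draws from its own substream, so tallies
// are independent of execution order.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_init(uint64_t seed, uint64_t stream) {
  // decorrelate the stream id before mixing it with the seed
  uint64_t s = stream;
  uint64_t mixed = splitmix64(s);
  uint64_t state = seed ^ mixed;
  // burn one draw so state 0 does not leak through
  splitmix64(state);
  return state;
}

// unbiased bounded draw in [0, n) by rejection
static inline uint32_t bounded_rand(uint64_t &state, uint32_t n) {
  uint64_t threshold = (~uint64_t(0) - n + 1) % n; // 2^64 mod n
  for (;;) {
    uint64_t r = splitmix64(state);
    if (r >= threshold) return (uint32_t)(r % n);
  }
}

// [[Rcpp::export]]
IntegerVector walk_ends_cpp(List adj, IntegerVector start_pool, int walk_length,
                            int n_repeats, double seed) {
  int n_nodes = adj.size();
  std::vector<std::vector<int>> nb(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end()); // 0-based neighbour indices
  }
  int n_pool = start_pool.size();
  uint64_t master = (uint64_t)seed;
  IntegerVector ends(n_repeats);
  for (int r = 0; r < n_repeats; ++r) {
    uint64_t state = stream_init(master, (uint64_t)r);
    int cur = start_pool[bounded_rand(state, (uint32_t)n_pool)]; // 0-based
    for (int step = 0; step < walk_length; ++step) {
      const std::vector<int> &nn = nb[cur];
      if (nn.empty()) break; // dead end: stay put
      cur = nn[bounded_rand(state, (uint32_t)nn.size())];
    }
    ends[r] = cur + 1; // 1-based for R
  }
  return ends;
}

// Monte-Carlo mean-contrast sampler: draws n_samples subsets of size k without
// replacement from `values` (pool restored between samples) and counts samples
// whose mean deviates from the pool mean at least as much as the observed
// category deviation. Ties count as exceedances (permutation convention).
// [[Rcpp::export]]
int contrast_exceed_cpp(NumericVector values, int k, double obs_dev,
                        int n_samples, double seed) {
  int n = values.size();
  std::vector<double> pool(values.begin(), values.end());
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += pool[i];
  double total_mean = total / n;
  uint64_t master = (uint64_t)seed;
  double tol = 1e-12 * (1.0 + std::abs(obs_dev));
  int exceed = 0;
  std::vector<double> work(pool);
  std::vector<uint32_t> picked(k);
  for (int s = 0; s < n_samples; ++s) {
    uint64_t state = stream_init(master, (uint64_t)s);
    // partial Fisher-Yates; swaps undone afterwards so the pool is restored
    double sum = 0.0;
    for (int i = 0; i < k; ++i) {
      uint32_t j = i + bounded_rand(state, (uint32_t)(n - i));
      picked[i] = j;
      std::swap(work[i], work[j]);
      sum += work[i];
    }
    double dev = std::abs(sum / k - total_mean);
    if (dev >= obs_dev - tol) ++exceed;
    for (int i = k - 1; i >= 0; --i) std::swap(work[i], work[picked[i]]);
  }
  return exceed;
}
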