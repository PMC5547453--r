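// Fox-Chen-Heath (FCH) minimal perfect hash: randomized construction core.
//
// Keys are 40-bit unsigned integers carried as R doubles (exact below 2^53);
// seeds are 48-bit so their doubles round-trip exactly through serialization.
// The three phases:
//   mapping   - a seeded mixer assigns each key a bucket (skewed split: a p1
//               fraction of keys into the first ceil(p2*b) buckets) and a
//               provisional slot in [0, n);
//   ordering  - buckets processed in non-increasing size, ties by index;
//   searching - per bucket, find displacement d with (slot + d) mod n free
//               for all its keys, probing d in a seeded full-coverage order
//               (random start + step coprime to n). Internal slot collisions
//               within a bucket are unresolvable by a common shift, so they
//               trigger an immediate seed redraw.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static const uint64_t MASK48 = (1ULL << 48) - 1;

// Shared by build and evaluate: bucket + provisional slot for one key.
// p1/p2 arrive as float32-quantized values so serialized functions evaluate
// identically after a round trip.
static inline void map_key(uint64_t key, uint64_t seed, int n, int b,
                           double p1, double p2, int* bucket, int* slot) {
  uint64_t h1 = mix64(key ^ mix64(seed ^ 0x5C5C5C5C5C5C5C5CULL));
  double frac = (double)(h1 >> 11) * (1.0 / 9007199254740992.0); // [0,1)
  int bh = (int)(p2 * b);
  if (bh < 1) bh = 1;
  if (bh > b) bh = b;
  int bk;
  if (frac < p1 || bh == b) {
    bk = (int)(frac / p1 * bh);
    if (bk >= bh) bk = bh - 1;
  } else {
    int bl = b - bh;
    bk = bh + (int)((frac - p1) / (1.0 - p1) * bl);
    if (bk >= b) bk = b - 1;
  }
  uint64_t h2 = mix64(key ^ mix64(seed ^ 0xA3A3A3A3A3A3A3A3ULL));
  *bucket = bk;
  *slot = (int)(h2 % (uint64_t)n);
}

static inline uint64_t gcd64(uint64_t a, uint64_t b) {
  while (b) { uint64_t t = a % b; a = b; b = t; }
  return a;
}

// One construction attempt under a fixed (seed_map, seed_probe) pair.
// Fills g (length b); returns true on success.
static bool attempt_build(const std::vector<uint64_t>& keys, int n, int b,
                          double p1, double p2, uint64_t seed_map,
                          uint64_t seed_probe, int probe_limit,
                          std::vector<int>& g) {
  std::vector<int> bucket(n), slot(n);
  std::vector<int> bsize(b, 0);
  for (int i = 0; i < n; ++i) {
    map_key(keys[i], seed_map, n, b, p1, p2, &bucket[i], &slot[i]);
    bsize[bucket[i]]++;
  }
  // Bucket membership lists (counting layout).
  std::vector<int> start(b + 1, 0);
  for (int j = 0; j < b; ++j) start[j + 1] = start[j] + bsize[j];
  std::vector<int> members(n);
  {
    std::vector<int> cur(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) members[cur[bucket[i]]++] = i;
  }
  // A bucket whose keys share a provisional slot can never be separated.
  std::vector<char> seen(n, 0);
  for (int j = 0; j < b; ++j) {
    if (bsize[j] < 2) continue;
    for (int t = start[j]; t < start[j + 1]; ++t) {
      int s = slot[members[t]];
      if (seen[s]) {
        for (int u = start[j]; u < t; ++u) seen[slot[members[u]]] = 0;
        return false;
      }
      seen[s] = 1;
    }
    for (int t = start[j]; t < start[j + 1]; ++t) seen[slot[members[t]]] = 0;
  }
  // Ordering: non-increasing size, ties by ascending index.
  std::vector<int> order(b);
  std::iota(order.begin(), order.end(), 0);
  std::stable_sort(order.begin(), order.end(), [&](int a, int c) {
    return bsize[a] > bsize[c];
  });
  // Searching.
  std::vector<char> occupied(n, 0);
  std::fill(g.begin(), g.end(), 0);
  int limit = std::min(probe_limit, n);
  for (int oi = 0; oi < b; ++oi) {
    int j = order[oi];
    if (bsize[j] == 0) continue;
    uint64_t hb = mix64(seed_probe ^ (uint64_t)(j + 1));
    int d0 = (int)(hb % (uint64_t)n);
    uint64_t step = 1;
    if (n > 1) {
      step = 1 + (hb >> 17) % (uint64_t)(n - 1);
      while (gcd64(step, (uint64_t)n) != 1) step = (step % (uint64_t)(n - 1)) + 1;
    }
    bool placed = false;
    for (int t = 0; t < limit && !placed; ++t) {
      int d = (int)(((uint64_t)d0 + (uint64_t)t * step) % (uint64_t)n);
      bool ok = true;
      for (int u = start[j]; u < start[j + 1] && ok; ++u)
        if (occupied[(slot[members[u]] + d) % n]) ok = false;
      if (ok) {
        for (int u = start[j]; u < start[j + 1]; ++u)
          occupied[(slot[members[u]] + d) % n] = 1;
        g[j] = d;
        placed = true;
      }
    }
    if (!placed) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".c_fch_build")]]
List c_fch_build(NumericVector keys, int b, double p1, double p2,
                 double rng_seed, int max_restarts, int probe_limit) {
  int n = keys.size();
  std::vector<uint64_t> k(n);
  for (int i = 0; i < n; ++i) k[i] = (uint64_t)keys[i];
  std::vector<int> g(b, 0);
  uint64_t base = mix64((uint64_t)rng_seed);
  for (int a = 0; a < max_restarts; ++a) {
    uint64_t seed_map = mix64(base + 2 * (uint64_t)a + 1) & MASK48;
    uint64_t seed_probe = mix64(base + 2 * (uint64_t)a + 2) & MASK48;
    if (attempt_build(k, n, b, p1, p2, seed_map, seed_probe, probe_limit, g)) {
      return List::create(
        _["success"] = true,
        _["seed_map"] = (double)seed_map,
        _["seed_probe"] = (double)seed_probe,
        _["g"] = IntegerVector(g.begin(), g.end()),
        _["attempts"] = a + 1);
    }
  }
  return List::create(_["success"] = false, _["attempts"] = max_restarts);
}

// [[Rcpp::export(name = ".c_fch_eval")]]
IntegerVector c_fch_eval(NumericVector keys, int n, int b, double p1, double p2,
                         double seed_map, IntegerVector g) {
  int m = keys.size();
  IntegerVector out(m);
  uint64_t seed = (uint64_t)seed_map;
  for (int i = 0; i < m; ++i) {
    int bucket, slot;
    map_key((uint64_t)keys[i], seed, n, b, p1, p2, &bucket, &slot);
    out[i] = (slot + g[bucket]) % n;
  }
  return out;
}

// Seeded 64-bit mixer exposed to R (top 32 bits as a double, hence exact);
// used for deterministic auxiliary randomness such as nonces in tests.
// [[Rcpp::export(name = ".c_mix32")]]
NumericVector c_mix32(NumericVector x, double seed) {
  int m = x.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = (double)(mix64((uint64_t)x[i] ^ mix64((uint64_t)seed)) >> 32);
  return out;
}
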