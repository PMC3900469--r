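#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform generator. Every stochastic draw in the optimizer is
// keyed by (seed, iteration, gene, island, particle, op), so the value of a
// draw depends only on its key, never on how many draws other workers made
// before it. This is what makes the worker-pool backend bit-identical to the
// sequential loop for any worker count.

static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t absorb(uint64_t s, uint64_t part) {
  return mix64(s ^ (part * 0xFF51AFD7ED558CCDULL + 0x9E3779B97F4A7C15ULL));
}

static uint64_t key_state(double seed, double iter, double gene,
                          double island, double particle, double op) {
  uint64_t s = 0x853C49E6748FEA9BULL;
  s = absorb(s, (uint64_t)(int64_t)seed);
  s = absorb(s, (uint64_t)(int64_t)iter);
  s = absorb(s, (uint64_t)(int64_t)gene);
  s = absorb(s, (uint64_t)(int64_t)island);
  s = absorb(s, (uint64_t)(int64_t)particle);
  s = absorb(s, (uint64_t)(int64_t)op);
  return s;
}

static inline double next_unif(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = mix64(s);
  return (double)(z >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

// [[Rcpp::export]]
NumericVector cxx_uniforms(double seed, double iter, double gene,
                           double island, double particle, double op, int n) {
  uint64_t s = key_state(seed, iter, gene, island, particle, op);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = next_unif(s);
  return out;
}

// One independent stream per particle id; rows follow `particles`.
// [[Rcpp::export]]
NumericMatrix cxx_uniform_matrix(double seed, double iter, double gene,
                                 double island, NumericVector particles,
                                 double op, int ncol) {
  int nrow = particles.size();
  NumericMatrix out(nrow, ncol);
  for (int i = 0; i < nrow; ++i) {
    uint64_t s = key_state(seed, iter, gene, island, particles[i], op);
    for (int j = 0; j < ncol; ++j) out(i, j) = next_unif(s);
  }
  return out;
}
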