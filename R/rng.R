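# Deterministic counter-based random streams.
#
# Every stochastic decision of the optimizer is drawn from a stream keyed by
# (run seed, iteration, gene, island, particle-or-slot, operation). A draw's
# value depends only on its key, so the same configuration yields bit-identical
# runs regardless of evaluation order or worker scheduling, and the map/reduce
# backend is exactly equivalent to the sequential loop.

# operation tags (stable; serialized runs depend on them)
OP_INIT <- 1L        # initial particle positions
OP_PSO_R1 <- 2L      # per-dimension r1 of the velocity update
OP_PSO_R2 <- 3L      # per-dimension r2 of the velocity update
OP_TOURNAMENT <- 4L  # tournament entrant indices
OP_CROSSOVER <- 5L   # per-dimension phi1/phi2 of the crossover
OP_MUTATION <- 6L    # mutation gate / direction / magnitude draws
OP_NEWCOMER <- 7L    # fresh random parent-pool individuals
OP_PARENT <- 8L      # which elites enter the parent pool
OP_MIGRATION <- 9L   # which donors migrate
OP_X0 <- 10L         # synthetic initial states

#' Keyed uniform random draws
#'
#' Draws `n` uniforms from the deterministic stream identified by the key
#' `(seed, iteration, gene, island, particle, op)`. Identical keys always
#' produce identical sequences; distinct keys produce independent streams.
#' This is the only source of randomness in the optimizer, which is why runs
#' are reproducible independently of execution order, worker count, and R's
#' global RNG state.
#'
#' @param seed Integer run seed.
#' @param n Number of variates.
#' @param iteration,gene,island,particle,op Integer key components.
#' @return Numeric vector of `n` values in `[0, 1)`.
#' @export
#' @examples
#' rng_uniforms(1, 3, iteration = 5, particle = 2)
rng_uniforms <- function(seed, n, iteration = 0L, gene = 0L, island = 0L,
                         particle = 0L, op = 0L) {
  cxx_uniforms(seed, iteration, gene, island, particle, op, as.integer(n))
}

# matrix of uniforms, one row per particle id
rng_matrix <- function(seed, iteration, gene, island, particles, op, ncol) {
  cxx_uniform_matrix(seed, iteration, gene, island, as.numeric(particles),
                     op, as.integer(ncol))
}
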