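# Shared fixtures, all generated in code.

# small noise-free benchmark (3 genes unless asked otherwise)
toy_benchmark <- function(n_genes = 3, seed = 7, ...) {
  generate_benchmark(benchmark_spec(n_genes, noise_sd = 0, seed = seed, ...))
}

# a fixed in-bounds 2-gene model with mild dynamics
toy_model2 <- function() {
  s_system(alpha = c(2, 1.5), beta = c(1.2, 2.5),
           g = matrix(c(0, -0.8, 1.2, 0), 2, 2, byrow = TRUE),
           h = matrix(c(1.1, 0, 0.4, 0.9), 2, 2, byrow = TRUE))
}

# quick config for engine tests
quick_cfg <- function(pop_size = 40, max_iterations = 15, seed = 3, ...) {
  gapso_config(pop_size = pop_size, max_iterations = max_iterations,
               seed = seed, ...)
}

# initialize engine island states directly (bypassing a run)
fresh_states <- function(seed, gene, island_ids, subpop, n_genes) {
  lapply(island_ids, function(id) {
    igapso:::init_island(seed, gene, id, subpop, igapso:::param_bounds(n_genes))
  })
}

wide_bounds <- function(d) list(lower = rep(-10, d), upper = rep(10, d))
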