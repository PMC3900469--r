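# Synthetic benchmarks.
#
# Emulates the role GeneNetWeaver plays for in-silico benchmarking: sample a
# sparse regulatory network, simulate perturbed time courses, and add
# microarray-like noise. Data are generated *from* S-systems, so ground-truth
# parameter recovery is well-posed -- a deliberate difference from GNW's
# kinetic model that enables stronger tests.

#' Benchmark specification
#'
#' @param n_genes Number of genes.
#' @param mean_in_degree Expected number of nonzero off-diagonal kinetic
#'   orders (g or h entries) per gene (default 2; must be below `n_genes`).
#' @param time_points Measurements per time course (default 31).
#' @param duration Length of the time course in model time units (default 2;
#'   long enough for both transient and near-steady behavior at the sampled
#'   rate constants).
#' @param n_perturbations Number of independently initialized time courses
#'   (default 1).
#' @param noise_sd Multiplicative log-normal noise sd (default 0.05; 0 for
#'   noise-free data).
#' @param noise_model `"lognormal"` (microarray-like, default) or
#'   `"additive"` Gaussian.
#' @param normalize Scale each gene to `(0, 1]` by its maximum after noise?
#'   Default `FALSE`.
#' @param seed Generator seed.
#' @return A `benchmark_spec` object.
#' @export
benchmark_spec <- function(n_genes, mean_in_degree = 2, time_points = 31,
                           duration = 2, n_perturbations = 1, noise_sd = 0.05,
                           noise_model = c("lognormal", "additive"),
                           normalize = FALSE, seed = 1) {
  noise_model <- match.arg(noise_model)
  if (time_points < 2) abort("time_points must be >= 2", class = "igapso_argument_error")
  if (mean_in_degree >= n_genes) {
    abort("mean_in_degree must be below n_genes", class = "igapso_argument_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "igapso_argument_error")
  structure(
    list(n_genes = as.integer(n_genes), mean_in_degree = mean_in_degree,
         time_points = as.integer(time_points), duration = duration,
         n_perturbations = as.integer(n_perturbations), noise_sd = noise_sd,
         noise_model = noise_model, normalize = normalize,
         seed = as.integer(seed)),
    class = "benchmark_spec"
  )
}

# run code under a temporary R RNG seed, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample a sparse S-system network
#'
#' Each off-diagonal `g[i, j]` and `h[i, j]` is nonzero with probability
#' `mean_in_degree / (2 (N - 1))`; nonzero kinetic orders are drawn uniformly
#' from `[-3, -0.5] U [0.5, 3]` (near-zero edges would be unidentifiable).
#' Rate constants come from `U[1, 5]`. Self-degradation `h[i, i] > 0` is
#' guaranteed so trajectories stay bounded; `g[i, i]` is fixed at 0.
#'
#' @param spec A [benchmark_spec()].
#' @return An [s_system()].
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  n <- spec$n_genes
  with_local_seed(spec$seed, {
    alpha <- runif(n, 1, 5)
    beta <- runif(n, 1, 5)
    q <- if (n > 1) spec$mean_in_degree / (2 * (n - 1)) else 0
    draw_orders <- function() {
      m <- matrix(0, n, n)
      if (n > 1) {
        off <- which(!diag(n))
        on <- off[runif(length(off)) < q]
        m[on] <- sample(c(-1, 1), length(on), replace = TRUE) *
          runif(length(on), 0.5, 3)
      }
      m
    }
    g <- draw_orders()
    h <- draw_orders()
    diag(g) <- 0
    diag(h) <- runif(n, 0.5, 3)
    s_system(alpha, beta, g, h)
  })
}

#' Generate perturbed noisy time courses from a model
#'
#' For each perturbation an initial state is drawn from `U[0.2, 1.2]` per
#' gene and the coupled system is integrated over `time_points` equally
#' spaced times in `[0, duration]`. Multiplicative log-normal (or additive
#' Gaussian) noise is applied, values are floored at the state floor, and
#' each gene is optionally max-normalized to `(0, 1]`. Initial states whose
#' trajectories diverge are redrawn up to 20 times.
#'
#' @param model An [s_system()].
#' @param spec A [benchmark_spec()].
#' @return A list of expression-dataset tibbles, one per perturbation.
#' @export
generate_dataset <- function(model, spec) {
  stopifnot(inherits(model, "s_system"), inherits(spec, "benchmark_spec"))
  times <- seq(0, spec$duration, length.out = spec$time_points)
  n <- n_genes(model)
  with_local_seed(spec$seed + 1L, {
    lapply(seq_len(spec$n_perturbations), function(p) {
      clean <- NULL
      for (try in 1:20) {
        x0 <- runif(n, 0.2, 1.2)
        clean <- tryCatch(simulate_coupled(model, x0, times),
                          igapso_divergence = function(e) NULL)
        if (!is.null(clean)) break
      }
      if (is.null(clean)) {
        abort("model trajectories diverge for all sampled initial states",
              class = "igapso_divergence")
      }
      vals <- dataset_matrix(clean)
      if (spec$noise_sd > 0) {
        noise <- matrix(rnorm(length(vals), 0, spec$noise_sd), nrow(vals))
        vals <- if (spec$noise_model == "lognormal") vals * exp(noise)
                else vals + noise
        vals <- pmax(vals, STATE_FLOOR)
      }
      if (spec$normalize) {
        vals <- sweep(vals, 2, apply(vals, 2, max), "/")
        vals <- pmax(vals, STATE_FLOOR)
      }
      new_dataset(times, vals, model$gene_names)
    })
  })
}

#' Generate a complete benchmark (network plus datasets)
#'
#' @param spec A [benchmark_spec()].
#' @return List with `model` (the ground-truth [s_system()]) and `datasets`
#'   (list of expression tibbles).
#' @export
generate_benchmark <- function(spec) {
  model <- generate_network(spec)
  list(model = model, datasets = generate_dataset(model, spec))
}
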