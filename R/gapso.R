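# Hybrid GA-PSO operators.
#
# One iteration of the optimizer ranks the population, keeps the best p
# fraction as elites (refined by constriction-factor PSO), discards the rest,
# and refills the population with children bred by a GA (tournament selection,
# velocity-aware midpoint crossover, non-uniform mutation) from a parent pool
# of PSO-improved elites plus a fraction r of fresh random individuals.

#' Optimizer configuration
#'
#' @param pop_size Population size per gene sub-problem (`>= 4`; thousands at
#'   production scale).
#' @param p_elite Fraction of the population kept as elites and refined by
#'   PSO (default 0.7).
#' @param r_random Fraction of the population regenerated at random into the
#'   parent pool each iteration (default 0.1).
#' @param r_final Optional end-of-run value for a linear schedule of
#'   `r_random`; `NULL` (default) keeps it static.
#' @param c1,c2 PSO acceleration constants; their sum `phi` must exceed 4
#'   (defaults 2.05/2.05, so `phi = 4.1`).
#' @param inertia_w Inertia weight `w` on the previous velocity (default 1, so
#'   the constriction factor alone governs momentum).
#' @param mutation_b Shape exponent of the non-uniform mutation (default 5).
#' @param mutation_prob Per-parameter mutation probability (default 0.1).
#' @param tournament_size Entrants per tournament (default 2, with
#'   replacement).
#' @param max_iterations Number of iterations (default 200).
#' @param substeps RK4 substeps per observed interval in fitness evaluation.
#' @param penalty_fitness Fitness assigned to divergent candidates.
#' @param seed Integer run seed; all optimizer randomness derives from it.
#' @return A `gapso_config` object.
#' @export
gapso_config <- function(pop_size = 500, p_elite = 0.7, r_random = 0.1,
                         r_final = NULL, c1 = 2.05, c2 = 2.05, inertia_w = 1,
                         mutation_b = 5, mutation_prob = 0.1,
                         tournament_size = 2, max_iterations = 200,
                         substeps = 10, penalty_fitness = PENALTY_FITNESS,
                         seed = 1) {
  if (pop_size < 4) abort("pop_size must be >= 4", class = "igapso_argument_error")
  if (p_elite <= 0 || p_elite >= 1) {
    abort("p_elite must lie in (0, 1)", class = "igapso_argument_error")
  }
  if (r_random < 0 || r_random > 1 - p_elite) {
    abort("r_random must lie in [0, 1 - p_elite]", class = "igapso_argument_error")
  }
  if (c1 + c2 <= 4) {
    abort("phi = c1 + c2 has to be larger than 4", class = "igapso_domain_error")
  }
  structure(
    list(pop_size = as.integer(pop_size), p_elite = p_elite,
         r_random = r_random, r_final = r_final, c1 = c1, c2 = c2,
         phi = c1 + c2, inertia_w = inertia_w, mutation_b = mutation_b,
         mutation_prob = mutation_prob,
         tournament_size = as.integer(tournament_size),
         max_iterations = as.integer(max_iterations),
         substeps = as.integer(substeps), penalty_fitness = penalty_fitness,
         seed = as.integer(seed)),
    class = "gapso_config"
  )
}

#' @export
print.gapso_config <- function(x, ...) {
  cat("<gapso_config>\n")
  for (nm in setdiff(names(x), "phi")) {
    cat(sprintf("  %-16s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  cat(sprintf("  %-16s %s (chi = %.6f)\n", "phi", format(x$phi),
              constriction_factor(x$phi)))
  invisible(x)
}

# randomness rate at iteration t (optionally on a linear ramp)
r_at <- function(cfg, iteration) {
  if (is.null(cfg$r_final)) return(cfg$r_random)
  cfg$r_random + (cfg$r_final - cfg$r_random) * iteration / cfg$max_iterations
}

# per-dimension search bounds of a 2(N+1)-parameter sub-problem
param_bounds <- function(n_genes) {
  list(
    lower = c(ALPHA_RANGE[1], rep(KINETIC_RANGE[1], n_genes),
              ALPHA_RANGE[1], rep(KINETIC_RANGE[1], n_genes)),
    upper = c(ALPHA_RANGE[2], rep(KINETIC_RANGE[2], n_genes),
              ALPHA_RANGE[2], rep(KINETIC_RANGE[2], n_genes))
  )
}

#' Clerc-Kennedy constriction factor
#'
#' `chi = 2 / |2 - phi - sqrt(phi^2 - 4 phi)|` for `phi > 4`; it damps PSO
#' velocities to balance exploration against exploitation.
#'
#' @param phi Sum of the acceleration constants, must exceed 4.
#' @return Scalar in (0, 1).
#' @export
#' @examples
#' constriction_factor(4.1) # ~0.7298
constriction_factor <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1 || !is.finite(phi) || phi <= 4) {
    abort("phi has to be larger than 4", class = "igapso_domain_error")
  }
  2 / abs(2 - phi - sqrt(phi^2 - 4 * phi))
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' PSO velocity and position update
#'
#' `v' = chi (w v + c1 r1 (pbest - x) + c2 r2 (gbest - x))`, `x' = x + v'`,
#' with fresh per-dimension uniforms `r1`, `r2`. Positions are clamped to the
#' search bounds and velocities to plus/minus the bound width. Accepts a
#' single particle (vectors) or a population (rows of conforming matrices).
#'
#' @param position,velocity,pbest Current state (vector of length `D` or
#'   `pop x D` matrices).
#' @param gbest Swarm-best position (length `D`).
#' @param cfg A [gapso_config()].
#' @param bounds List with `lower`/`upper` vectors of length `D`.
#' @param r1,r2 Optional pinned uniforms (same shape as `position`); drawn
#'   from `stats::runif` when omitted. The run engine always supplies keyed
#'   draws here.
#' @return List with updated `position` and `velocity`.
#' @export
pso_update <- function(position, velocity, pbest, gbest, cfg, bounds,
                       r1 = NULL, r2 = NULL) {
  pos <- rbind(position)
  vel <- rbind(velocity)
  pb <- rbind(pbest)
  gb <- matrix(gbest, nrow(pos), ncol(pos), byrow = TRUE)
  if (is.null(r1)) r1 <- matrix(runif(length(pos)), nrow(pos))
  if (is.null(r2)) r2 <- matrix(runif(length(pos)), nrow(pos))
  chi <- constriction_factor(cfg$phi)
  v <- chi * (cfg$inertia_w * vel + cfg$c1 * rbind(r1) * (pb - pos) +
                cfg$c2 * rbind(r2) * (gb - pos))
  lo <- matrix(bounds$lower, nrow(pos), ncol(pos), byrow = TRUE)
  hi <- matrix(bounds$upper, nrow(pos), ncol(pos), byrow = TRUE)
  v <- clamp(v, -(hi - lo), hi - lo)
  x <- clamp(pos + v, lo, hi)
  if (is.matrix(position)) list(position = x, velocity = v)
  else list(position = as.numeric(x), velocity = as.numeric(v))
}

#' Elite/parent-pool partition counts
#'
#' Best `floor(p * pop)` particles become elites; the worst `pop - n_elite`
#' are discarded and replaced by GA offspring bred from a parent pool of the
#' same size, containing `floor(r * pop)` fresh random individuals with the
#' remainder drawn from the elites.
#'
#' @param pop_size Population size.
#' @param p_elite,r_random Partition fractions.
#' @return List with `n_elite`, `n_pool`, `n_random`, `n_from_elite`.
#' @export
#' @examples
#' partition_counts(10, 0.7, 0.1) # 7 elites, pool = 1 random + 2 elites
partition_counts <- function(pop_size, p_elite, r_random) {
  n_elite <- floor(p_elite * pop_size)
  n_pool <- pop_size - n_elite
  n_random <- min(floor(r_random * pop_size), n_pool)
  list(n_elite = n_elite, n_pool = n_pool, n_random = n_random,
       n_from_elite = n_pool - n_random)
}

#' Rank a population and partition it into elites and discards
#'
#' Sorts ascending by fitness (minimization), breaking ties by particle id,
#' and applies [partition_counts()].
#'
#' @param fitness Evaluated fitness values; must contain no `NA`.
#' @param cfg A [gapso_config()] (its `p_elite`/`r_random` are used).
#' @param ids Tie-breaking particle ids (default positional).
#' @param r_random Optional override of the randomness rate (the engine
#'   passes the scheduled value).
#' @return List with `order` (ranked indices), `elite` (indices of the elite
#'   rows in ranked order), and the partition counts.
#' @export
rank_and_partition <- function(fitness, cfg, ids = seq_along(fitness),
                               r_random = cfg$r_random) {
  if (anyNA(fitness)) {
    abort("all fitness values must be evaluated before ranking",
          class = "igapso_state_error")
  }
  ord <- order(fitness, ids)
  cnt <- partition_counts(length(fitness), cfg$p_elite, r_random)
  c(list(order = ord, elite = ord[seq_len(cnt$n_elite)]), cnt)
}

#' Tournament selection
#'
#' Picks `k` entrants uniformly with replacement and returns the index of the
#' fittest (lowest fitness; ties to the lowest index).
#'
#' @param fitness Pool fitness values.
#' @param k Tournament size.
#' @param u Optional pinned uniforms (length `k`); the engine supplies keyed
#'   draws.
#' @return Index of the selected pool member.
#' @export
tournament_select <- function(fitness, k = 2, u = NULL) {
  n <- length(fitness)
  if (n == 0) abort("empty parent pool", class = "igapso_state_error")
  if (is.null(u)) u <- runif(k)
  entrants <- pmin(floor(u * n) + 1L, n)
  as.integer(entrants[which.min(fitness[entrants])])
}

#' Velocity-aware midpoint crossover
#'
#' From parents `old1`, `old2` creates two children at the parents' midpoint,
#' displaced by the other parent's velocity scaled by fresh per-dimension
#' uniforms: `new1 = (x1 + x2)/2 - phi1 * v2`, `new2 = (x1 + x2)/2 - phi2 *
#' v1`. Coordinates outside the search range are set to the violated bound;
#' children start with zero velocity.
#'
#' @param x1,v1,x2,v2 Parent positions and velocities (length `D`).
#' @param bounds List with `lower`/`upper`.
#' @param phi1,phi2 Optional pinned uniforms (length `D`).
#' @return List with `child1` and `child2` position vectors.
#' @export
crossover <- function(x1, v1, x2, v2, bounds, phi1 = NULL, phi2 = NULL) {
  if (length(x1) != length(x2)) {
    abort("parents must share dimensionality", class = "igapso_dimension_error")
  }
  if (is.null(phi1)) phi1 <- runif(length(x1))
  if (is.null(phi2)) phi2 <- runif(length(x1))
  mid <- (x1 + x2) / 2
  list(child1 = clamp(mid - phi1 * v2, bounds$lower, bounds$upper),
       child2 = clamp(mid - phi2 * v1, bounds$lower, bounds$upper))
}

# Michalewicz decay: a value in [0, y] that contracts towards 0 as t -> T
delta_nonuniform <- function(t, y, u, max_iterations, b) {
  y * (1 - u^((1 - t / max_iterations)^b))
}

#' Non-uniform mutation
#'
#' Each parameter mutates with probability `mutation_prob`; a mutated value
#' moves towards one bound by `Delta(t, y) = y (1 - u^((1 - t/T)^b))`, so
#' perturbations span the whole feasible range early in the run and shrink to
#' fine tuning as `t` approaches `max_iterations`.
#'
#' @param position Parameter vector (or matrix with particles in rows).
#' @param iteration Current iteration `t <= max_iterations`.
#' @param cfg A [gapso_config()].
#' @param bounds List with `lower`/`upper`.
#' @param u Optional pinned uniforms: list with `gate`, `dir`, `mag`, each
#'   shaped like `position`.
#' @return Mutated position, always within bounds.
#' @export
nonuniform_mutate <- function(position, iteration, cfg, bounds, u = NULL) {
  pos <- rbind(position)
  if (iteration > cfg$max_iterations) {
    abort("iteration exceeds max_iterations", class = "igapso_argument_error")
  }
  if (is.null(u)) {
    u <- list(gate = matrix(runif(length(pos)), nrow(pos)),
              dir = matrix(runif(length(pos)), nrow(pos)),
              mag = matrix(runif(length(pos)), nrow(pos)))
  }
  lo <- matrix(bounds$lower, nrow(pos), ncol(pos), byrow = TRUE)
  hi <- matrix(bounds$upper, nrow(pos), ncol(pos), byrow = TRUE)
  gate <- rbind(u$gate) < cfg$mutation_prob
  up <- rbind(u$dir) < 0.5
  mag <- rbind(u$mag)
  d_up <- delta_nonuniform(iteration, hi - pos, mag, cfg$max_iterations,
                           cfg$mutation_b)
  d_dn <- delta_nonuniform(iteration, pos - lo, mag, cfg$max_iterations,
                           cfg$mutation_b)
  out <- pos + gate * ifelse(up, d_up, -d_dn)
  out <- clamp(out, lo, hi)
  if (is.matrix(position)) out else as.numeric(out)
}
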