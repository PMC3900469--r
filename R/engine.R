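# Iteration engine.
#
# One iteration is executed as a map phase followed by a reduce phase -- the
# same split a mapper/reducer deployment uses, so the sequential loop and the
# worker-pool backend are the same algorithm executed by different schedulers:
#
#   map    (per particle, embarrassingly parallel): PSO velocity/position
#          update of the flagged elites, fitness evaluation of every stale
#          particle (moved elites, newborn children, fresh random pool
#          individuals), personal-best update.
#   reduce (grouped by gene, islands within): ranking, elite/discard
#          partition, sticky global-best update, synchronized migration at
#          epoch boundaries, GA reproduction (tournament selection, crossover,
#          non-uniform mutation) refilling the population.
#
# Relative to the classic presentation of the loop (rank, PSO on elites, GA,
# merge), the boundary is rotated so that all per-particle work lands in one
# phase: the ranking that opens an iteration in the classic flow here closes
# the previous reduce. The sequence of operations over a whole run is
# identical.
#
# Island state layout (internal): list(pos, vel, fit, pb_pos, pb_fit, elite,
# gbest_pos, gbest_fit, newc_pos, newc_fit, island_id). Rows are ranked order
# after each reduce; a particle's id is its row slot.

init_island <- function(seed, gene, island_id, subpop, bounds) {
  d <- length(bounds$lower)
  u <- rng_matrix(seed, 0L, gene, island_id, 0:(subpop - 1), OP_INIT, d)
  lo <- matrix(bounds$lower, subpop, d, byrow = TRUE)
  hi <- matrix(bounds$upper, subpop, d, byrow = TRUE)
  pos <- lo + u * (hi - lo)
  list(pos = pos, vel = matrix(0, subpop, d), fit = rep(NA_real_, subpop),
       pb_pos = pos, pb_fit = rep(Inf, subpop),
       elite = rep(FALSE, subpop), gbest_pos = rep(NA_real_, d),
       gbest_fit = Inf, newc_pos = NULL, newc_fit = NULL,
       island_id = as.integer(island_id))
}

# evaluate rows of a position matrix, optionally split across forked workers
eval_positions <- function(pos, data, gene, cfg, workers) {
  if (nrow(pos) == 0) return(numeric(0))
  gene0 <- gene - 1L
  if (workers <= 1 || nrow(pos) < 2 * workers) {
    return(fitness_batch(pos, data, gene0, substeps = cfg$substeps,
                         penalty = cfg$penalty_fitness))
  }
  chunks <- split(seq_len(nrow(pos)), cut(seq_len(nrow(pos)), workers, labels = FALSE))
  out <- parallel::mclapply(chunks, function(idx) {
    fitness_batch(pos[idx, , drop = FALSE], data, gene0,
                  substeps = cfg$substeps, penalty = cfg$penalty_fitness)
  }, mc.cores = workers)
  unlist(out, use.names = FALSE)
}

# map phase for one island
map_island <- function(st, data, gene, cfg, iteration, r_now, workers = 1) {
  bounds <- param_bounds(n_genes(data))
  isl <- st$island_id
  rows <- which(st$elite)
  if (length(rows) > 0) {
    d <- ncol(st$pos)
    r1 <- rng_matrix(cfg$seed, iteration, gene, isl, rows - 1L, OP_PSO_R1, d)
    r2 <- rng_matrix(cfg$seed, iteration, gene, isl, rows - 1L, OP_PSO_R2, d)
    upd <- pso_update(st$pos[rows, , drop = FALSE], st$vel[rows, , drop = FALSE],
                      st$pb_pos[rows, , drop = FALSE], st$gbest_pos, cfg,
                      bounds, r1, r2)
    st$pos[rows, ] <- upd$position
    st$vel[rows, ] <- upd$velocity
    st$fit[rows] <- NA_real_
  }
  stale <- which(is.na(st$fit))
  if (length(stale) > 0) {
    st$fit[stale] <- eval_positions(st$pos[stale, , drop = FALSE], data, gene,
                                    cfg, workers)
  }
  impr <- st$fit < st$pb_fit
  if (any(impr)) {
    st$pb_pos[impr, ] <- st$pos[impr, , drop = FALSE]
    st$pb_fit[impr] <- st$fit[impr]
  }
  cnt <- partition_counts(nrow(st$pos), cfg$p_elite, r_now)
  if (cnt$n_random > 0) {
    d <- ncol(st$pos)
    u <- rng_matrix(cfg$seed, iteration, gene, isl, 0:(cnt$n_random - 1),
                    OP_NEWCOMER, d)
    lo <- matrix(bounds$lower, cnt$n_random, d, byrow = TRUE)
    hi <- matrix(bounds$upper, cnt$n_random, d, byrow = TRUE)
    st$newc_pos <- lo + u * (hi - lo)
    st$newc_fit <- eval_positions(st$newc_pos, data, gene, cfg, workers)
  } else {
    st$newc_pos <- NULL
    st$newc_fit <- NULL
  }
  st$elite <- rep(FALSE, nrow(st$pos))
  st
}

rank_island <- function(st) {
  ord <- order(st$fit, seq_along(st$fit))
  st$pos <- st$pos[ord, , drop = FALSE]
  st$vel <- st$vel[ord, , drop = FALSE]
  st$fit <- st$fit[ord]
  st$pb_pos <- st$pb_pos[ord, , drop = FALSE]
  st$pb_fit <- st$pb_fit[ord]
  st
}

update_gbest <- function(st) {
  b <- which.min(st$pb_fit)
  if (length(b) == 1 && st$pb_fit[b] < st$gbest_fit) {
    st$gbest_fit <- st$pb_fit[b]
    st$gbest_pos <- st$pb_pos[b, ]
  }
  st
}

# sample n indices from 1..m without replacement (with replacement if n > m)
keyed_sample <- function(m, n, u) {
  if (n == 0) return(integer(0))
  if (n > m) return(pmin(floor(u * m) + 1L, m))
  remaining <- seq_len(m)
  out <- integer(n)
  for (j in seq_len(n)) {
    pick <- min(floor(u[j] * length(remaining)) + 1L, length(remaining))
    out[j] <- remaining[pick]
    remaining <- remaining[-pick]
  }
  out
}

# GA reproduction for one ranked island: breed n_pool children from the
# parent pool (fresh newcomers + draws from the elites)
breed_island <- function(st, gene, cfg, iteration, r_now, bounds) {
  subpop <- nrow(st$pos)
  d <- ncol(st$pos)
  isl <- st$island_id
  cnt <- partition_counts(subpop, cfg$p_elite, r_now)
  st$elite <- c(rep(TRUE, cnt$n_elite), rep(FALSE, subpop - cnt$n_elite))
  if (cnt$n_pool == 0) return(st)
  pe_u <- rng_uniforms(cfg$seed, max(cnt$n_from_elite, 1), iteration = iteration,
                       gene = gene, island = isl, op = OP_PARENT)
  pe_idx <- keyed_sample(cnt$n_elite, cnt$n_from_elite, pe_u)
  pool_pos <- rbind(st$newc_pos, st$pos[pe_idx, , drop = FALSE])
  pool_vel <- rbind(matrix(0, cnt$n_random, d), st$vel[pe_idx, , drop = FALSE])
  pool_fit <- c(st$newc_fit, st$fit[pe_idx])
  n_pool <- cnt$n_pool
  child_pos <- matrix(NA_real_, n_pool, d)
  n_pairs <- ceiling(n_pool / 2)
  k <- cfg$tournament_size
  for (cc in seq_len(n_pairs)) {
    ut <- rng_uniforms(cfg$seed, 2 * k, iteration = iteration, gene = gene,
                       island = isl, particle = cc - 1L, op = OP_TOURNAMENT)
    i1 <- tournament_select(pool_fit, k, ut[seq_len(k)])
    i2 <- tournament_select(pool_fit, k, ut[k + seq_len(k)])
    up <- rng_uniforms(cfg$seed, 2 * d, iteration = iteration, gene = gene,
                       island = isl, particle = cc - 1L, op = OP_CROSSOVER)
    ch <- crossover(pool_pos[i1, ], pool_vel[i1, ], pool_pos[i2, ],
                    pool_vel[i2, ], bounds, up[seq_len(d)], up[d + seq_len(d)])
    child_pos[2 * cc - 1, ] <- ch$child1
    if (2 * cc <= n_pool) child_pos[2 * cc, ] <- ch$child2
  }
  um <- rng_matrix(cfg$seed, iteration, gene, isl, 0:(n_pool - 1), OP_MUTATION,
                   3 * d)
  child_pos <- nonuniform_mutate(
    child_pos, iteration, cfg, bounds,
    u = list(gate = um[, seq_len(d), drop = FALSE],
             dir = um[, d + seq_len(d), drop = FALSE],
             mag = um[, 2 * d + seq_len(d), drop = FALSE])
  )
  rows <- cnt$n_elite + seq_len(n_pool)
  st$pos[rows, ] <- child_pos
  st$vel[rows, ] <- 0
  st$fit[rows] <- NA_real_
  st$pb_pos[rows, ] <- child_pos
  st$pb_fit[rows] <- Inf
  st$newc_pos <- NULL
  st$newc_fit <- NULL
  st
}

# reduce phase over all islands of one gene
reduce_islands <- function(states, gene, cfg, island_cfg, iteration, r_now) {
  states <- lapply(states, rank_island)
  states <- lapply(states, update_gbest)
  migrating <- length(states) > 1 && !is.null(island_cfg) &&
    iteration %% island_cfg$migration_interval == 0
  if (migrating) {
    states <- migrate(states, island_cfg, iteration = iteration, gene = gene,
                      seed = cfg$seed)
    states <- lapply(states, rank_island)
    states <- lapply(states, update_gbest)
  }
  bounds <- param_bounds(ncol(states[[1]]$pos) / 2 - 1)
  lapply(states, breed_island, gene = gene, cfg = cfg, iteration = iteration,
         r_now = r_now, bounds = bounds)
}

# full run for one gene sub-problem
run_core <- function(data, gene, cfg, island_cfg = NULL, workers = 1,
                     island_ids = NULL, spill_dir = NULL) {
  check_dataset(data)
  gi <- resolve_gene(colnames(data)[-1], gene)
  n_isl <- if (is.null(island_cfg)) 1L else island_cfg$n_islands
  subpop <- if (!is.null(island_cfg) && !is.null(island_cfg$subpop_size)) {
    island_cfg$subpop_size
  } else {
    if (cfg$pop_size %% n_isl != 0) {
      abort("pop_size must divide evenly across islands",
            class = "igapso_argument_error")
    }
    cfg$pop_size %/% n_isl
  }
  if (is.null(island_ids)) island_ids <- seq_len(n_isl) - 1L
  bounds <- param_bounds(n_genes(data))
  states <- lapply(island_ids, function(id) {
    init_island(cfg$seed, gi, id, subpop, bounds)
  })
  traces <- matrix(NA_real_, cfg$max_iterations, n_isl)
  for (t in seq_len(cfg$max_iterations)) {
    r_now <- r_at(cfg, t)
    if (workers > 1 && n_isl > 1) {
      states <- parallel::mclapply(states, map_island, data = data, gene = gi,
                                   cfg = cfg, iteration = t, r_now = r_now,
                                   mc.cores = min(workers, n_isl))
    } else {
      states <- lapply(states, map_island, data = data, gene = gi, cfg = cfg,
                       iteration = t, r_now = r_now, workers = workers)
    }
    states <- reduce_islands(states, gi, cfg, island_cfg, t, r_now)
    traces[t, ] <- vapply(states, function(s) s$gbest_fit, 0)
    if (!is.null(spill_dir)) {
      write_records(states_to_records(states, gi),
                    file.path(spill_dir, sprintf("gene%d_iter%04d.tsv", gi, t)))
    }
  }
  best_isl <- which.min(vapply(states, function(s) s$gbest_fit, 0))
  best <- states[[best_isl]]
  trace <- tibble::tibble(
    iteration = rep(seq_len(cfg$max_iterations), n_isl),
    island = rep(island_ids, each = cfg$max_iterations),
    gbest = as.vector(traces)
  )
  list(gene = gi, gene_name = colnames(data)[gi + 1],
       par = as.numeric(best$gbest_pos), fitness = best$gbest_fit,
       trace = trace, states = states)
}

#' Run the hybrid GA-PSO on one gene sub-problem
#'
#' Optimizes the `2(N+1)` decoupled parameters of one gene against a
#' time-series dataset with a single swarm.
#'
#' @param data Expression dataset: a data frame whose first column is `time`
#'   and whose remaining columns are positive gene concentrations.
#' @param gene Gene index (1-based) or column name.
#' @param cfg A [gapso_config()].
#' @param workers Fork-pool size for the map phase (results are identical for
#'   any value).
#' @return A `gapso_run`: list with the best parameter vector `par`, its
#'   `fitness`, and the per-iteration `trace` tibble of the best-so-far
#'   fitness.
#' @export
run_gapso <- function(data, gene, cfg = gapso_config(), workers = 1) {
  out <- run_core(data, gene, cfg, island_cfg = NULL, workers = workers)
  out$states <- NULL
  class(out) <- "gapso_run"
  out
}

#' Run the island-model GA-PSO (iGA-PSO) on one gene sub-problem
#'
#' Splits the population across hypercube islands that evolve independently
#' and exchange migrants at synchronized intervals; with one island this is
#' exactly [run_gapso()].
#'
#' @inheritParams run_gapso
#' @param island_cfg An [island_config()].
#' @param spill_dir Optional directory: when set, the particle records of
#'   every iteration are spilled as tab-separated text (see
#'   [write_records()]).
#' @return A `gapso_run` whose `trace` has one row per iteration and island.
#' @export
run_igapso <- function(data, gene, cfg = gapso_config(),
                       island_cfg = island_config(), workers = 1,
                       spill_dir = NULL) {
  out <- run_core(data, gene, cfg, island_cfg = island_cfg, workers = workers,
                  spill_dir = spill_dir)
  out$states <- NULL
  class(out) <- "gapso_run"
  out
}

#' @export
print.gapso_run <- function(x, ...) {
  cat("<gapso_run> gene ", x$gene_name, ": best fitness ",
      format(x$fitness, digits = 6), " after ",
      max(x$trace$iteration), " iterations\n", sep = "")
  invisible(x)
}
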