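# Coarse-grained island model.
#
# The population is split into 2^n subpopulations placed on the nodes of a
# binary n-cube. Each island runs the GA-PSO independently; every
# `migration_interval` iterations a synchronized communication phase sends
# copies of randomly chosen top-fraction particles to each immediate
# hypercube neighbor, where they replace the worst particles. Migration
# preserves island sizes and keeps diversity across islands, which is what
# lets the same total population reach better fitness than a single panmictic
# swarm.

#' Island-model configuration
#'
#' @param n_islands Number of islands; powers of two map onto a binary
#'   hypercube, other counts fall back to a bidirectional ring.
#' @param migration_interval Iterations between synchronized migrations
#'   (default 10).
#' @param migration_fraction Fraction of a subpopulation sent to each
#'   neighbor, and likewise the worst fraction replaced there (default 0.05).
#' @param donor_fraction Top fraction of a subpopulation eligible as migrants
#'   (default 0.20).
#' @param subpop_size Particles per island; when `NULL` the optimizer divides
#'   its `pop_size` evenly across islands.
#' @return An `island_config` object.
#' @export
island_config <- function(n_islands = 4, migration_interval = 10,
                          migration_fraction = 0.05, donor_fraction = 0.20,
                          subpop_size = NULL) {
  if (n_islands < 1) abort("n_islands must be >= 1", class = "igapso_argument_error")
  if (migration_interval < 1) {
    abort("migration_interval must be >= 1", class = "igapso_argument_error")
  }
  if (migration_fraction < 0 || migration_fraction > donor_fraction ||
      donor_fraction > 1) {
    abort("need 0 <= migration_fraction <= donor_fraction <= 1",
          class = "igapso_argument_error")
  }
  structure(
    list(n_islands = as.integer(n_islands),
         migration_interval = as.integer(migration_interval),
         migration_fraction = migration_fraction,
         donor_fraction = donor_fraction,
         subpop_size = if (is.null(subpop_size)) NULL else as.integer(subpop_size)),
    class = "island_config"
  )
}

#' @export
print.island_config <- function(x, ...) {
  cat("<island_config> ", x$n_islands, " islands, migrate every ",
      x$migration_interval, " iterations (", 100 * x$migration_fraction,
      "% from top ", 100 * x$donor_fraction, "%)\n", sep = "")
  invisible(x)
}

#' Immediate neighbors on the island topology
#'
#' Islands are labeled `0 .. n_islands - 1`. For a power-of-two count the
#' topology is the binary hypercube: neighbors differ in exactly one bit of
#' their id. Other counts fall back to a bidirectional ring.
#'
#' @param island_id Island id, `0 <= island_id < n_islands`.
#' @param n_islands Number of islands.
#' @return Sorted integer vector of neighbor ids.
#' @export
#' @examples
#' hypercube_neighbors(0, 8) # 1 2 4
hypercube_neighbors <- function(island_id, n_islands) {
  if (island_id < 0 || island_id >= n_islands) {
    abort("island_id out of range", class = "igapso_argument_error")
  }
  if (n_islands == 1) return(integer(0))
  if (bitwAnd(n_islands, n_islands - 1L) == 0L) {
    bits <- 2^(seq_len(log2(n_islands)) - 1)
    sort(vapply(bits, function(b) bitwXor(as.integer(island_id), as.integer(b)), 0L))
  } else {
    sort(unique(c((island_id - 1) %% n_islands, (island_id + 1) %% n_islands)))
  }
}

# migrants sent per donor per communication phase (round half up, >= 1)
migration_count <- function(cfg, subpop_size) {
  if (cfg$migration_fraction <= 0) return(0L)
  max(1L, as.integer(floor(cfg$migration_fraction * subpop_size + 0.5)))
}

#' Synchronized migration between hypercube neighbors
#'
#' From each island's snapshot, `k = round(migration_fraction * subpop)`
#' migrants are drawn (without replacement, keyed draws) from its top
#' `donor_fraction` particles; copies -- position, velocity, fitness and
#' pbest -- replace the currently worst `k` particles of every immediate
#' neighbor. Incoming batches are applied in ascending neighbor-id order, so
#' a later batch may displace an earlier migrant that is still among the
#' worst. Island sizes never change; donors keep their particles.
#'
#' @param islands List of island states, each a list with `pos`, `vel`,
#'   `fit`, `pb_pos`, `pb_fit` matrices/vectors of one subpopulation (rows =
#'   particles). [run_igapso()] maintains these internally; tests may build
#'   them directly.
#' @param cfg An [island_config()].
#' @param iteration,gene,seed Key components for the migrant draws.
#' @return The list of island states after migration.
#' @export
migrate <- function(islands, cfg, iteration = 0L, gene = 0L, seed = 0L) {
  n_isl <- length(islands)
  sizes <- vapply(islands, function(s) nrow(s$pos), 0L)
  if (length(unique(sizes)) != 1) {
    abort("all islands must have equal subpopulation sizes",
          class = "igapso_state_error")
  }
  subpop <- sizes[1]
  k <- migration_count(cfg, subpop)
  if (k == 0L || n_isl == 1) return(islands)
  n_top <- max(1L, floor(cfg$donor_fraction * subpop))
  # snapshot donors before any replacement
  migrants <- vector("list", n_isl)
  for (d in seq_len(n_isl)) {
    st <- islands[[d]]
    ord <- order(st$fit, seq_along(st$fit))
    top <- ord[seq_len(n_top)]
    u <- rng_uniforms(seed, max(k, 1), iteration = iteration, gene = gene,
                      island = d - 1L, op = OP_MIGRATION)
    chosen <- integer(k)
    remaining <- top
    for (j in seq_len(k)) {
      if (length(remaining) == 0) remaining <- top # k > n_top: recycle
      pick <- min(floor(u[j] * length(remaining)) + 1L, length(remaining))
      chosen[j] <- remaining[pick]
      remaining <- remaining[-pick]
    }
    migrants[[d]] <- list(
      pos = st$pos[chosen, , drop = FALSE],
      vel = st$vel[chosen, , drop = FALSE],
      fit = st$fit[chosen],
      pb_pos = st$pb_pos[chosen, , drop = FALSE],
      pb_fit = st$pb_fit[chosen]
    )
  }
  for (rcv in seq_len(n_isl)) {
    for (nb in hypercube_neighbors(rcv - 1L, n_isl)) {
      st <- islands[[rcv]]
      worst <- rev(order(st$fit, seq_along(st$fit)))[seq_len(k)]
      mg <- migrants[[nb + 1L]]
      st$pos[worst, ] <- mg$pos
      st$vel[worst, ] <- mg$vel
      st$fit[worst] <- mg$fit
      st$pb_pos[worst, ] <- mg$pb_pos
      st$pb_fit[worst] <- mg$pb_fit
      islands[[rcv]] <- st
    }
  }
  islands
}
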