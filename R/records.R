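# Particle records.
#
# The execution backend's unit of data is one particle per line of text,
# carrying the identifier triple (gene, island, particle) plus the full
# search state. The record stream is what a mapper/reducer deployment would
# ship between phases; the local backend keeps it in memory and can spill it
# to files for inspection. Field order is declared (and versioned) in the
# file header.

RECORD_VERSION <- "igapso-records-v1"
RECORD_SCALARS <- c("gene_id", "island_id", "particle_id", "role", "dim",
                    "fitness", "pbest_fitness", "island_best_fitness")
RECORD_VECTORS <- c("position", "velocity", "pbest_position",
                    "island_best_position", "gbest_position")

fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Serialize particle records to text lines
#'
#' One tab-separated line per particle: `gene_id`, `island_id`,
#' `particle_id`, `role`, the dimensionality, the fitness scalars, then the
#' position, velocity, personal-best, island-best and swarm-best vectors at
#' 17 significant digits. `parse_records(serialize_records(x))` is the
#' identity.
#'
#' @param records A record tibble as produced by [as_particle_records()].
#' @return Character vector: a versioned header line followed by one line per
#'   record.
#' @export
serialize_records <- function(records) {
  if (any(vapply(records$position, function(p) any(is.infinite(p)), TRUE))) {
    abort("non-finite particle state cannot be serialized",
          class = "igapso_serialize_error")
  }
  header <- paste0("#", RECORD_VERSION, " fields=",
                   paste(c(RECORD_SCALARS, RECORD_VECTORS), collapse = ","))
  lines <- vapply(seq_len(nrow(records)), function(r) {
    paste(c(records$gene_id[r], records$island_id[r], records$particle_id[r],
            records$role[r], length(records$position[[r]]),
            fmt17(records$fitness[r]), fmt17(records$pbest_fitness[r]),
            fmt17(records$island_best_fitness[r]),
            fmt17(records$position[[r]]), fmt17(records$velocity[[r]]),
            fmt17(records$pbest_position[[r]]),
            fmt17(records$island_best_position[[r]]),
            fmt17(records$gbest_position[[r]])),
          collapse = "\t")
  }, character(1))
  c(header, lines)
}

#' Parse particle records from text lines
#'
#' @param lines Character vector as produced by [serialize_records()].
#' @return A particle-record tibble.
#' @export
parse_records <- function(lines) {
  lines <- lines[!startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(li) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      abort(paste0("record line ", li, ": malformed at field ", length(f) + 1,
                   " (need at least 5 fields)"),
            class = "igapso_parse_error")
    }
    d <- suppressWarnings(as.integer(f[5]))
    expected <- 8 + 5 * d
    if (is.na(d) || length(f) != expected) {
      bad <- if (is.na(d)) 5 else min(length(f) + 1, expected + 1)
      abort(paste0("record line ", li, ": malformed at field ", bad,
                   " (expected ", expected, " fields, got ", length(f), ")"),
            class = "igapso_parse_error")
    }
    num <- function(idx) {
      v <- suppressWarnings(as.numeric(f[idx]))
      v[f[idx] == "NA"] <- NA_real_
      v
    }
    vec_at <- function(k) num(8 + (k - 1) * d + seq_len(d))
    tibble::tibble(
      gene_id = as.integer(f[1]), island_id = as.integer(f[2]),
      particle_id = as.integer(f[3]), role = f[4],
      fitness = num(6), pbest_fitness = num(7), island_best_fitness = num(8),
      position = list(vec_at(1)), velocity = list(vec_at(2)),
      pbest_position = list(vec_at(3)), island_best_position = list(vec_at(4)),
      gbest_position = list(vec_at(5))
    )
  })
  dplyr::bind_rows(rows)
}

#' Write/read particle record files
#'
#' Plain-text spill files in the versioned one-particle-per-line format.
#'
#' @param records A particle-record tibble.
#' @param path File path.
#' @return `read_records()` returns the record tibble; `write_records()`
#'   returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  writeLines(serialize_records(records), path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  parse_records(readLines(path))
}

# ---- engine state <-> records -------------------------------------------

states_to_records <- function(states, gene) {
  gfits <- vapply(states, function(s) s$gbest_fit, 0)
  bi <- which.min(gfits)
  gbest <- if (is.finite(gfits[bi])) states[[bi]]$gbest_pos else
    rep(NA_real_, ncol(states[[1]]$pos))
  recs <- lapply(states, function(st) {
    subpop <- nrow(st$pos)
    role <- ifelse(st$elite, "elite", ifelse(is.na(st$fit), "child", "member"))
    base <- tibble::tibble(
      gene_id = gene, island_id = st$island_id,
      particle_id = seq_len(subpop) - 1L, role = role,
      fitness = st$fit, pbest_fitness = st$pb_fit,
      island_best_fitness = st$gbest_fit,
      position = lapply(seq_len(subpop), function(r) st$pos[r, ]),
      velocity = lapply(seq_len(subpop), function(r) st$vel[r, ]),
      pbest_position = lapply(seq_len(subpop), function(r) st$pb_pos[r, ]),
      island_best_position = rep(list(as.numeric(st$gbest_pos)), subpop),
      gbest_position = rep(list(as.numeric(gbest)), subpop)
    )
    if (!is.null(st$newc_pos) && nrow(st$newc_pos) > 0) {
      nn <- nrow(st$newc_pos)
      newc <- tibble::tibble(
        gene_id = gene, island_id = st$island_id,
        particle_id = subpop + seq_len(nn) - 1L, role = "newcomer",
        fitness = st$newc_fit, pbest_fitness = st$newc_fit,
        island_best_fitness = st$gbest_fit,
        position = lapply(seq_len(nn), function(r) st$newc_pos[r, ]),
        velocity = rep(list(rep(0, ncol(st$newc_pos))), nn),
        pbest_position = lapply(seq_len(nn), function(r) st$newc_pos[r, ]),
        island_best_position = rep(list(as.numeric(st$gbest_pos)), nn),
        gbest_position = rep(list(as.numeric(gbest)), nn)
      )
      base <- dplyr::bind_rows(base, newc)
    }
    base
  })
  dplyr::bind_rows(recs)
}

records_to_states <- function(records) {
  stopifnot(length(unique(records$gene_id)) == 1)
  states <- lapply(sort(unique(records$island_id)), function(isl) {
    rec <- records[records$island_id == isl, ]
    rec <- rec[order(rec$particle_id), ]
    pop <- rec[rec$role != "newcomer", ]
    newc <- rec[rec$role == "newcomer", ]
    st <- list(
      pos = do.call(rbind, pop$position),
      vel = do.call(rbind, pop$velocity),
      fit = pop$fitness,
      pb_pos = do.call(rbind, pop$pbest_position),
      pb_fit = pop$pbest_fitness,
      elite = pop$role == "elite",
      gbest_pos = pop$island_best_position[[1]],
      gbest_fit = pop$island_best_fitness[1],
      newc_pos = if (nrow(newc) > 0) do.call(rbind, newc$position) else NULL,
      newc_fit = if (nrow(newc) > 0) newc$fitness else NULL,
      island_id = as.integer(isl)
    )
    st
  })
  list(states = states, gene = records$gene_id[1])
}

#' Expose the current optimizer state as particle records
#'
#' Internal engine states become one record per particle; useful for
#' inspecting or spilling the search state between phases.
#'
#' @param states Engine island states (as held by the run loop).
#' @param gene 1-based gene index of the sub-problem.
#' @return A particle-record tibble.
#' @export
as_particle_records <- function(states, gene) {
  states_to_records(states, gene)
}

# ---- map / reduce phase surface -----------------------------------------

#' Map phase: per-particle operations
#'
#' Applies the embarrassingly parallel operations to every record of one
#' iteration: PSO velocity/position update for elite-flagged particles,
#' fitness evaluation of all stale particles (including fresh random
#' parent-pool individuals generated here), and personal-best update. The
#' result is identical for any `workers` because every random draw is keyed
#' by (seed, iteration, gene, island, particle, op), never by execution
#' order.
#'
#' @param records Particle-record tibble for one gene.
#' @param data Expression dataset.
#' @param cfg A [gapso_config()].
#' @param iteration Iteration number (1-based).
#' @param workers Fork-pool size.
#' @return Updated record tibble (newcomer records appended).
#' @export
map_phase <- function(records, data, cfg, iteration, workers = 1) {
  s <- records_to_states(records)
  r_now <- r_at(cfg, iteration)
  states <- lapply(s$states, map_island, data = data, gene = s$gene, cfg = cfg,
                   iteration = iteration, r_now = r_now, workers = workers)
  states_to_records(states, s$gene)
}

#' Reduce phase: grouped operations
#'
#' Groups records by gene (islands within): ranking and elite/discard
#' partition, sticky best update, synchronized migration at epoch boundaries,
#' and GA reproduction (tournament selection, crossover, non-uniform
#' mutation) consuming the newcomer records. Every output record of the gene
#' group carries the same swarm-best (`gbest_position`) broadcast.
#'
#' @inheritParams map_phase
#' @param island_cfg An [island_config()] or `NULL` for a single swarm.
#' @return Updated record tibble (children are stale, `fitness = NA`, until
#'   the next map phase).
#' @export
reduce_phase <- function(records, cfg, island_cfg = NULL, iteration = 1) {
  if (anyNA(records$fitness)) {
    abort("reduce phase observed stale fitness; run map_phase first",
          class = "igapso_state_error")
  }
  out <- lapply(split(records, records$gene_id), function(rec) {
    s <- records_to_states(rec)
    states <- reduce_islands(s$states, s$gene, cfg, island_cfg, iteration,
                             r_at(cfg, iteration))
    states_to_records(states, s$gene)
  })
  dplyr::bind_rows(out)
}
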