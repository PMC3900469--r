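test_that("hypercube neighbors are single-bit flips and the topology is symmetric", {
  expect_equal(hypercube_neighbors(0, 8), c(1, 2, 4))
  expect_equal(hypercube_neighbors(0, 2), 1)
  expect_equal(hypercube_neighbors(3, 4), c(1, 2))
  for (n in c(2, 4, 8)) {
    for (a in 0:(n - 1)) {
      for (b in hypercube_neighbors(a, n)) {
        expect_true(a %in% hypercube_neighbors(b, n))
      }
    }
  }
  # non-power-of-two counts fall back to a bidirectional ring
  expect_equal(hypercube_neighbors(0, 3), c(1, 2))
  expect_equal(hypercube_neighbors(1, 6), c(0, 2))
  expect_error(hypercube_neighbors(5, 4), class = "igapso_argument_error")
})

test_that("migrant counts round half-up from the subpopulation fraction", {
  cfg <- island_config(migration_fraction = 0.05)
  expect_equal(igapso:::migration_count(cfg, 40), 2)
  expect_equal(igapso:::migration_count(cfg, 125), 6)
  expect_equal(igapso:::migration_count(cfg, 10), 1) # minimum of one
  cfg0 <- island_config(migration_fraction = 0)
  expect_equal(igapso:::migration_count(cfg0, 40), 0)
})

test_that("migration copies top-donor particles over neighbors' worst and conserves sizes", {
  set.seed(1) # only for building the synthetic swarm states
  subpop <- 40; d <- 4
  mk <- function(isl) {
    pos <- matrix(runif(subpop * d), subpop)
    list(pos = pos, vel = matrix(0, subpop, d),
         fit = sort(runif(subpop, 1, 10)) + isl, # ranked order, distinct ranges
         pb_pos = pos, pb_fit = sort(runif(subpop, 0.5, 9)) + isl)
  }
  islands <- lapply(0:3, mk)
  pre <- islands
  cfg <- island_config(n_islands = 4)
  out <- migrate(islands, cfg, iteration = 10, seed = 3)
  k <- igapso:::migration_count(cfg, subpop)
  expect_equal(k, 2)
  for (i in 1:4) {
    expect_equal(nrow(out[[i]]$pos), subpop)
    changed <- which(out[[i]]$fit != pre[[i]]$fit)
    nbs <- hypercube_neighbors(i - 1, 4) + 1
    # every changed slot now holds a copy of some top-20% particle of a neighbor
    for (s in changed) {
      src <- vapply(nbs, function(nb) {
        any(abs(pre[[nb]]$fit - out[[i]]$fit[s]) < 1e-15)
      }, TRUE)
      expect_true(any(src))
      donor <- nbs[which(src)[1]]
      thr <- sort(pre[[donor]]$fit)[max(1, floor(0.2 * subpop))]
      expect_lte(out[[i]]$fit[s], thr)
    }
    # only worst slots were replaced: survivors of the original population
    # that outrank the migrants are untouched
    expect_true(all(pre[[i]]$fit[seq_len(subpop - 3 * k)] %in% out[[i]]$fit))
  }
  small <- mk(9)
  small <- lapply(small, function(x) if (is.matrix(x)) x[1:30, ] else x[1:30])
  expect_error(migrate(c(out, small = list(small)), cfg),
               class = "igapso_state_error")
})

test_that("a single island reduces exactly to the plain GA-PSO", {
  d <- toy_benchmark()$datasets[[1]]
  cfg <- quick_cfg()
  r1 <- run_gapso(d, 1, cfg)
  ri <- run_igapso(d, 1, cfg, island_config(n_islands = 1, subpop_size = cfg$pop_size))
  expect_identical(r1$trace$gbest, ri$trace$gbest)
  expect_identical(r1$par, ri$par)
})

test_that("with zero migration, islands match isolated runs under per-island seeds", {
  d <- toy_benchmark()$datasets[[1]]
  cfg <- quick_cfg(pop_size = 24, max_iterations = 10)
  icfg <- island_config(n_islands = 2, subpop_size = 12, migration_fraction = 0,
                        donor_fraction = 0)
  arch <- igapso:::run_core(d, 1, cfg, island_cfg = icfg)
  for (isl in 0:1) {
    solo <- igapso:::run_core(d, 1, cfg,
                              island_cfg = island_config(n_islands = 1, subpop_size = 12),
                              island_ids = isl)
    expect_identical(solo$trace$gbest,
                     arch$trace$gbest[arch$trace$island == isl])
  }
})

test_that("island runs keep the global best non-increasing across epochs", {
  d <- toy_benchmark()$datasets[[1]]
  cfg <- quick_cfg(pop_size = 32, max_iterations = 20)
  ri <- run_igapso(d, 2, cfg,
                   island_config(n_islands = 4, subpop_size = 8, migration_interval = 5))
  best_per_iter <- tapply(ri$trace$gbest, ri$trace$iteration, min)
  expect_true(all(diff(best_per_iter) <= 0))
  expect_equal(ri$fitness, min(ri$trace$gbest))
})
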