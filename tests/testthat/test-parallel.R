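test_that("particle records serialize and parse losslessly", {
  states <- fresh_states(9, 2L, 0:1, 6, 3)
  recs <- as_particle_records(states, 2L)
  lines <- serialize_records(recs)
  expect_true(startsWith(lines[1], "#igapso-records-v1"))
  back <- parse_records(lines)
  expect_equal(back, recs)
  # file round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(recs, path)
  expect_equal(read_records(path), recs)
})

test_that("records differing only in particle_id differ only in that field", {
  states <- fresh_states(9, 1L, 0L, 4, 2)
  recs <- as_particle_records(states, 1L)
  r2 <- recs[1, ]
  r2$particle_id <- 99L
  r2$position <- recs$position[1]
  l1 <- strsplit(serialize_records(recs[1, ])[2], "\t")[[1]]
  l2 <- strsplit(serialize_records(r2)[2], "\t")[[1]]
  expect_equal(which(l1 != l2), 3L)
})

test_that("malformed record lines raise a parse error naming the field", {
  states <- fresh_states(9, 1L, 0L, 2, 2)
  good <- serialize_records(as_particle_records(states, 1L))[2]
  fields <- strsplit(good, "\t")[[1]]
  bad <- paste(fields[-length(fields)], collapse = "\t")
  expect_error(parse_records(bad), "field", class = "igapso_parse_error")
  expect_error(parse_records("1\t2\t3"), class = "igapso_parse_error")
  # non-finite state refuses to serialize
  recs <- as_particle_records(states, 1L)
  recs$position[[1]][1] <- Inf
  expect_error(serialize_records(recs), class = "igapso_serialize_error")
})

test_that("map then reduce reproduces one in-process engine iteration exactly", {
  d <- toy_benchmark()$datasets[[1]]
  cfg <- quick_cfg(pop_size = 20, max_iterations = 6, seed = 11)
  icfg <- island_config(n_islands = 2, subpop_size = 10, migration_interval = 2)
  eng <- igapso:::run_core(d, 1, cfg, island_cfg = icfg)
  recs <- as_particle_records(fresh_states(cfg$seed, 1L, 0:1, 10, 3), 1L)
  for (t in 1:cfg$max_iterations) {
    n_in <- sum(recs$role != "newcomer")
    recs <- map_phase(recs, d, cfg, iteration = t)
    # map conserves the population and evaluates every particle
    expect_equal(sum(recs$role != "newcomer"), n_in)
    expect_false(anyNA(recs$fitness))
    recs <- reduce_phase(recs, cfg, island_cfg = icfg, iteration = t)
    expect_equal(sum(recs$role != "newcomer"), n_in)
  }
  expect_equal(recs, as_particle_records(eng$states, 1L))
  # every record of the gene group carries the same swarm-best broadcast
  expect_length(unique(recs$gbest_position), 1)
})

test_that("map phase output is identical for any worker count", {
  d <- toy_benchmark()$datasets[[1]]
  cfg <- quick_cfg(pop_size = 16, max_iterations = 4)
  recs <- as_particle_records(fresh_states(cfg$seed, 1L, 0L, 16, 3), 1L)
  m1 <- map_phase(recs, d, cfg, iteration = 1, workers = 1)
  m4 <- map_phase(recs, d, cfg, iteration = 1, workers = 4)
  expect_equal(m1, m4)
})

test_that("an evaluated particle at its own best with matching swarm best is a fixed point", {
  d <- toy_benchmark()$datasets[[1]]
  cfg <- quick_cfg(pop_size = 8, max_iterations = 4, r_random = 0)
  st <- fresh_states(cfg$seed, 1L, 0L, 8, 3)[[1]]
  st$fit <- fitness_batch_ <- igapso:::eval_positions(st$pos, d, 1L, cfg, 1)
  st$pb_pos <- st$pos
  st$pb_fit <- st$fit
  b <- which.min(st$fit)
  st$gbest_pos <- st$pos[b, ]
  st$gbest_fit <- st$fit[b]
  st$elite[b] <- TRUE
  out <- igapso:::map_island(st, d, 1L, cfg, iteration = 2, r_now = 0)
  expect_equal(out$pos[b, ], st$pos[b, ])
  expect_equal(out$vel[b, ], rep(0, ncol(st$pos)))
  expect_equal(out$fit[b], st$fit[b])
})

test_that("the reduce phase refuses stale fitness", {
  d <- toy_benchmark()$datasets[[1]]
  cfg <- quick_cfg(pop_size = 8, max_iterations = 3)
  recs <- as_particle_records(fresh_states(cfg$seed, 1L, 0L, 8, 3), 1L)
  expect_error(reduce_phase(recs, cfg, iteration = 1),
               class = "igapso_state_error")
})

test_that("spill files mirror the record format", {
  d <- toy_benchmark()$datasets[[1]]
  cfg <- quick_cfg(pop_size = 10, max_iterations = 3)
  dir <- withr::local_tempdir()
  run_igapso(d, 1, cfg, island_config(n_islands = 1, subpop_size = 10),
             spill_dir = dir)
  files <- list.files(dir, pattern = "^gene1_iter")
  expect_length(files, 3)
  recs <- read_records(file.path(dir, files[1]))
  expect_equal(sum(recs$role != "newcomer"), 10)
})
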