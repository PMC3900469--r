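test_that("constriction factor matches the closed form and its constraints", {
  expect_equal(constriction_factor(4.1), 0.729844, tolerance = 1e-6)
  expect_error(constriction_factor(4.0), class = "igapso_domain_error")
  expect_error(constriction_factor(3), class = "igapso_domain_error")
  grid <- seq(4.01, 10, length.out = 50)
  chis <- vapply(grid, constriction_factor, 0)
  expect_true(all(diff(chis) < 0))
  expect_true(all(chis > 0 & chis < 1))
})

test_that("PSO update has the expected fixed point and hand value", {
  cfg <- quick_cfg()
  b <- wide_bounds(3)
  # at pbest == gbest == x with zero velocity nothing moves
  x <- c(1, -2, 0.5)
  upd <- pso_update(x, rep(0, 3), x, x, cfg, b)
  expect_equal(upd$position, x)
  expect_equal(upd$velocity, rep(0, 3))

  # 1-D hand evaluation with pinned r1 = r2 = 1: v = chi * 4.1
  b1 <- wide_bounds(1)
  upd1 <- pso_update(0, 0, 1, 1, cfg, b1, r1 = 1, r2 = 1)
  expect_equal(upd1$position, constriction_factor(4.1) * 4.1, tolerance = 1e-5)
  expect_equal(upd1$position, 2.99236, tolerance = 1e-5)
})

test_that("PSO updates always land inside the bounds", {
  cfg <- quick_cfg()
  bounds <- igapso:::param_bounds(2)
  d <- length(bounds$lower)
  for (k in 1:25) {
    u <- rng_uniforms(5, 4 * d, particle = k)
    pos <- bounds$lower + u[1:d] * (bounds$upper - bounds$lower)
    vel <- (u[d + 1:d] - 0.5) * 20
    pb <- bounds$lower + u[2 * d + 1:d] * (bounds$upper - bounds$lower)
    gb <- bounds$lower + u[3 * d + 1:d] * (bounds$upper - bounds$lower)
    upd <- pso_update(pos, vel, pb, gb, cfg, bounds)
    expect_true(all(upd$position >= bounds$lower & upd$position <= bounds$upper))
    expect_true(all(abs(upd$velocity) <= bounds$upper - bounds$lower))
  }
})

test_that("partition counts follow the floor-then-remainder rule", {
  expect_equal(partition_counts(10, 0.7, 0.1),
               list(n_elite = 7, n_pool = 3, n_random = 1, n_from_elite = 2))
  expect_equal(partition_counts(9, 0.7, 0.1),
               list(n_elite = 6, n_pool = 3, n_random = 0, n_from_elite = 3))
  # degenerate pure-PSO partition
  expect_equal(partition_counts(10, 1, 0)$n_pool, 0)
  # conservation for arbitrary settings
  for (pop in c(5, 8, 40, 125, 500)) {
    cnt <- partition_counts(pop, 0.7, 0.1)
    expect_equal(cnt$n_elite + cnt$n_pool, pop)
    expect_equal(cnt$n_random + cnt$n_from_elite, cnt$n_pool)
  }
})

test_that("ranking refuses stale fitness and orders ascending with stable ties", {
  cfg <- quick_cfg()
  expect_error(rank_and_partition(c(1, NA, 2), cfg), class = "igapso_state_error")
  rp <- rank_and_partition(c(3, 1, 1, 2), cfg)
  expect_equal(rp$order, c(2, 3, 4, 1))
})

test_that("tournament selection matches exact win probabilities", {
  # best-of-k with replacement over n ranked members:
  # P(rank j wins) = ((n-j+1)^k - (n-j)^k) / n^k
  n <- 4; k <- 3
  fit <- c(0.1, 0.2, 0.3, 0.4)
  wins <- table(factor(vapply(1:10000, function(i) {
    tournament_select(fit, k, u = rng_uniforms(42, k, particle = i))
  }, 0L), levels = 1:n))
  exact <- (((n:1)^k - (n - 1:n)^k) / n^k)
  expect_equal(as.numeric(wins) / 10000, exact, tolerance = 0.03)
  # k = 1 is uniform: all members selected sometimes
  picks <- vapply(1:2000, function(i) {
    tournament_select(fit, 1, u = rng_uniforms(43, 1, particle = i))
  }, 0L)
  expect_equal(sort(unique(picks)), 1:4)
  # ties resolve deterministically under pinned draws
  same <- rep(1, 5)
  expect_identical(tournament_select(same, 2, u = c(0.9, 0.1)),
                   tournament_select(same, 2, u = c(0.9, 0.1)))
  expect_error(tournament_select(numeric(0)), class = "igapso_state_error")
})

test_that("crossover midpoints, hand values, and bound handling", {
  b <- wide_bounds(2)
  # identical parents with zero velocity reproduce the parent
  ch <- crossover(c(1, 2), c(0, 0), c(1, 2), c(0, 0), b)
  expect_equal(ch$child1, c(1, 2))
  expect_equal(ch$child2, c(1, 2))
  # 1-D hand case: mid = 1, phi = 0.5, v = 1 -> 0.5
  b1 <- wide_bounds(1)
  ch1 <- crossover(0, 1, 2, 1, b1, phi1 = 0.5, phi2 = 0.5)
  expect_equal(ch1$child1, 0.5)
  expect_equal(ch1$child2, 0.5)
  # a coordinate beyond the range is set to the bound
  bn <- list(lower = 0, upper = 1)
  ch2 <- crossover(0.9, 0, 0.9, -5, bn, phi1 = 1, phi2 = 1)
  expect_equal(ch2$child1, 1)
  expect_error(crossover(1:2, 1:2, 1:3, 1:3, b), class = "igapso_dimension_error")
})

test_that("zero-velocity crossover children stay in the parents' convex hull", {
  bounds <- igapso:::param_bounds(2)
  d <- length(bounds$lower)
  for (k in 1:25) {
    u <- rng_uniforms(6, 2 * d, particle = k)
    x1 <- bounds$lower + u[1:d] * (bounds$upper - bounds$lower)
    x2 <- bounds$lower + u[d + 1:d] * (bounds$upper - bounds$lower)
    ch <- crossover(x1, rep(0, d), x2, rep(0, d), bounds,
                    phi1 = rng_uniforms(7, d, particle = k),
                    phi2 = rng_uniforms(8, d, particle = k))
    expect_true(all(ch$child1 >= pmin(x1, x2) & ch$child1 <= pmax(x1, x2)))
    expect_true(all(ch$child2 >= pmin(x1, x2) & ch$child2 <= pmax(x1, x2)))
  }
})

test_that("non-uniform mutation respects its limits and bounds", {
  cfg <- quick_cfg(max_iterations = 100)
  b <- list(lower = rep(0, 3), upper = rep(10, 3))
  x <- c(2, 5, 9)
  pin <- function(gate, dir, mag) {
    list(gate = matrix(gate, 1, 3), dir = matrix(dir, 1, 3),
         mag = matrix(mag, 1, 3))
  }
  # u = 1 leaves parameters unchanged
  expect_equal(nonuniform_mutate(x, 10, cfg, b, u = pin(0, 0, 1)), x)
  # final iteration leaves parameters unchanged regardless of u
  expect_equal(nonuniform_mutate(x, 100, cfg, b, u = pin(0, 0.9, 0.01)), x)
  # gate above the probability: no mutation
  expect_equal(nonuniform_mutate(x, 10, cfg, b, u = pin(0.99, 0, 0.1)), x)
  expect_error(nonuniform_mutate(x, 101, cfg, b), class = "igapso_argument_error")
  # bound property over many pinned mutations: in range, |delta| <= gap
  for (k in 1:40) {
    u3 <- rng_uniforms(11, 9, particle = k)
    mut <- nonuniform_mutate(x, 1 + (k %% 99), cfg, b,
                             u = pin(u3[1:3] * 0.1, u3[4:6], u3[7:9]))
    expect_true(all(mut >= b$lower & mut <= b$upper))
    up <- mut >= x
    expect_true(all(abs(mut - x) <= ifelse(up, b$upper - x, x - b$lower) + 1e-12))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(gapso_config(pop_size = 3), class = "igapso_argument_error")
  expect_error(gapso_config(p_elite = 1), class = "igapso_argument_error")
  expect_error(gapso_config(r_random = 0.4), class = "igapso_argument_error")
  expect_error(gapso_config(c1 = 2, c2 = 2), class = "igapso_domain_error")
  # linear r schedule interpolates between endpoints
  cfg <- gapso_config(r_random = 0.1, r_final = 0.3, max_iterations = 100)
  expect_equal(igapso:::r_at(cfg, 0), 0.1)
  expect_equal(igapso:::r_at(cfg, 50), 0.2)
  expect_equal(igapso:::r_at(cfg, 100), 0.3)
})
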