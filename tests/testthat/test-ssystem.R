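test_that("coupled simulation matches closed forms on degenerate models", {
  # zero exponents: dx/dt = alpha - beta, linear growth
  m <- s_system(alpha = 2, beta = 1, g = matrix(0), h = matrix(0))
  out <- simulate_coupled(m, x0 = 1, times = c(0, 1))
  expect_equal(out$G1, c(1, 2), tolerance = 1e-12)

  # alpha == beta and g == h: derivative identically zero
  g <- matrix(c(0.5, -1, 0.3, 0.8), 2, 2)
  m2 <- s_system(c(3, 2), c(3, 2), g, g)
  out2 <- simulate_coupled(m2, c(0.7, 1.4), seq(0, 2, by = 0.5))
  expect_true(all(abs(out2$G1 - 0.7) < 1e-12))
  expect_true(all(abs(out2$G2 - 1.4) < 1e-12))
})

test_that("RK4 trajectories agree with a refined-step reference and show 4th-order convergence", {
  m <- toy_model2()
  x0 <- c(0.6, 1.1)
  times <- seq(0, 2, length.out = 21)
  ref <- dataset_matrix(simulate_coupled(m, x0, times, substeps = 1000))
  coarse <- dataset_matrix(simulate_coupled(m, x0, times, substeps = 10))
  expect_lt(max(abs(coarse - ref)), 1e-6)

  err <- function(s) max(abs(dataset_matrix(simulate_coupled(m, x0, times, substeps = s)) - ref))
  # halving the step should cut the error by at least 8x (4th-order behavior)
  expect_gt(err(2) / err(4), 8)
})

test_that("simulation guards invalid inputs and signals divergence", {
  m <- toy_model2()
  expect_error(simulate_coupled(m, c(-1, 1), 0:1), class = "igapso_argument_error")
  expect_error(simulate_coupled(m, c(1, 1), c(1, 0)), class = "igapso_argument_error")
  expect_error(s_system(Inf, 1, matrix(0), matrix(0)), class = "igapso_invalid_model")
  expect_error(s_system(11, 1, matrix(0), matrix(0)), class = "igapso_invalid_model")
  # strong self-activation blows up and must be reported, not returned
  bad <- s_system(10, 0, matrix(3), matrix(0), gene_names = "G1")
  expect_error(simulate_coupled(bad, 5, seq(0, 50, by = 1)),
               class = "igapso_divergence")
})

test_that("decoupled simulation reduces to the coupled system for N = 1", {
  m <- s_system(alpha = 2.5, beta = 1.5, g = matrix(0.4), h = matrix(1.2))
  times <- seq(0, 2, length.out = 11)
  coupled <- simulate_coupled(m, 0.8, times)
  pred <- simulate_decoupled_gene(gene_parameters(m, 1), coupled, 1)
  expect_equal(pred, coupled$G1, tolerance = 1e-9)
})

test_that("zero rate constants freeze the decoupled profile at its initial value", {
  b <- toy_benchmark()
  d <- b$datasets[[1]]
  par <- rep(0, 2 * (3 + 1))
  pred <- simulate_decoupled_gene(par, d, 2)
  expect_true(all(pred == d$G2[1]))
})

test_that("true parameters reproduce a noise-free profile through the decoupled model", {
  # dense sampling so interpolation of the other genes is not the bottleneck
  m <- toy_model2()
  times <- seq(0, 2, length.out = 201)
  d <- simulate_coupled(m, c(0.6, 1.1), times)
  for (i in 1:2) {
    pred <- simulate_decoupled_gene(gene_parameters(m, i), d, i)
    expect_lt(max(abs(pred - d[[i + 1]])), 1e-4)
  }
})

test_that("decoupled profiles ignore genes with zero kinetic orders", {
  b <- toy_benchmark()
  d <- b$datasets[[1]]
  par <- gene_parameters(b$model, 1)
  n <- 3
  # find a gene with no influence on gene 1 (or force one)
  par[1 + 2] <- 0   # g_{1,2}
  par[n + 2 + 2] <- 0 # h_{1,2}
  pred <- simulate_decoupled_gene(par, d, 1)
  d2 <- d
  d2$G2 <- d2$G2 * 3 + 0.5
  expect_identical(simulate_decoupled_gene(par, d2, 1), pred)
})

test_that("fitness is the printed sum of squared relative errors", {
  expect_identical(fitness_mse(1:5 / 2, 1:5 / 2), 0)
  expect_equal(fitness_mse(rep(3, 4), rep(2, 4)), 1.0)
  expect_equal(fitness_mse(rep(3, 4), rep(2, 4), normalize = TRUE), 0.25)
  expect_error(fitness_mse(c(1, 1), c(1, 0)), class = "igapso_domain_error")
  expect_error(fitness_mse(1:3, 1:2), class = "igapso_dimension_error")
  expect_identical(fitness_mse(c(1, NaN), c(1, 1)), 1e9)
  # non-negative, zero iff identical
  for (k in 1:20) {
    des <- rng_uniforms(99, 6, particle = k) + 0.5
    pred <- des + (rng_uniforms(98, 6, particle = k) - 0.5)
    f <- fitness_mse(pred, des)
    expect_gte(f, 0)
    if (f == 0) expect_equal(pred, des)
  }
})

test_that("parameter counts follow the coupled and decoupled formulas", {
  expect_equal(unlist(parameter_counts(25)), c(coupled_total = 1300, per_gene = 52))
  expect_equal(unlist(parameter_counts(1)), c(coupled_total = 4, per_gene = 4))
  for (n in c(2, 5, 10, 100)) {
    pc <- parameter_counts(n)
    expect_equal(pc$per_gene * n, pc$coupled_total)
  }
  expect_error(parameter_counts(0), class = "igapso_argument_error")
})

test_that("per-gene vectors round-trip through assembly", {
  b <- toy_benchmark(4)
  vecs <- lapply(1:4, gene_parameters, model = b$model)
  expect_equal(length(vecs[[1]]), 2 * (4 + 1))
  m2 <- assemble_model(vecs, gene_names = b$model$gene_names)
  expect_equal(m2, b$model)
})

test_that("tidiers expose parameters and summary", {
  m <- toy_model2()
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 2 + 2 * 4)
  expect_equal(td$value[td$parameter == "g" & td$gene == "G1" & td$regulator == "G2"],
               m$g[1, 2])
  gl <- glance(m)
  expect_equal(gl$n_parameters, 12)
})
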