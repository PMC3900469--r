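# S-system models and their simulation.
#
# An S-system describes each gene's expression rate as the difference of two
# power laws,
#   dx_i/dt = alpha_i * prod_j x_j^g_ij - beta_i * prod_j x_j^h_ij,
# where alpha_i, beta_i >= 0 are rate constants and the kinetic orders g_ij,
# h_ij encode the sign and strength of gene j's influence on gene i's
# production and degradation. Inferring a coupled N-gene model means fitting
# all 2N(N+1) parameters at once; the decoupled formulation fits each gene's
# 2(N+1) parameters independently, substituting observed profiles for the
# other genes.

ALPHA_RANGE <- c(0, 10)
KINETIC_RANGE <- c(-3, 3)
STATE_FLOOR <- 1e-6
STATE_CAP <- 1e6
PENALTY_FITNESS <- 1e9

#' Construct an S-system model
#'
#' @param alpha,beta Non-negative rate constants, length `N`, in `[0, 10]`.
#' @param g,h `N x N` kinetic-order matrices in `[-3, 3]`; `g[i, j]` is the
#'   influence of gene `j` on gene `i`'s production, `h[i, j]` on its
#'   degradation.
#' @param gene_names Optional gene labels (default `G1..GN`).
#' @return An object of class `s_system`.
#' @export
#' @examples
#' m <- s_system(alpha = 2, beta = 1, g = matrix(0), h = matrix(0))
#' simulate_coupled(m, x0 = 1, times = 0:2)
s_system <- function(alpha, beta, g, h, gene_names = NULL) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  g <- as.matrix(g)
  h <- as.matrix(h)
  n <- length(alpha)
  if (length(beta) != n || !all(dim(g) == n) || !all(dim(h) == n)) {
    abort("alpha, beta, g and h must be shape-consistent for one N",
          class = "igapso_dimension_error")
  }
  if (!all(is.finite(alpha), is.finite(beta), is.finite(g), is.finite(h))) {
    abort("model parameters must be finite", class = "igapso_invalid_model")
  }
  if (any(alpha < ALPHA_RANGE[1] | alpha > ALPHA_RANGE[2]) ||
      any(beta < ALPHA_RANGE[1] | beta > ALPHA_RANGE[2])) {
    abort("rate constants must lie in [0, 10]", class = "igapso_invalid_model")
  }
  if (any(abs(g) > KINETIC_RANGE[2]) || any(abs(h) > KINETIC_RANGE[2])) {
    abort("kinetic orders must lie in [-3, 3]", class = "igapso_invalid_model")
  }
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  structure(
    list(alpha = alpha, beta = beta, g = unname(g), h = unname(h),
         gene_names = as.character(gene_names)),
    class = "s_system"
  )
}

#' @export
print.s_system <- function(x, ...) {
  n <- n_genes(x)
  edges <- sum((x$g != 0 | x$h != 0) & !diag(n))
  cat("<s_system> ", n, " genes, ", edges, " regulatory edges, ",
      2 * n * (n + 1), " parameters\n", sep = "")
  invisible(x)
}

#' Number of genes in a model or dataset
#' @param x An `s_system` or expression dataset.
#' @return Integer gene count.
#' @export
n_genes <- function(x) UseMethod("n_genes")

#' @export
n_genes.s_system <- function(x) length(x$alpha)

#' @export
n_genes.data.frame <- function(x) ncol(x) - 1L

#' Parameter counts of the coupled and decoupled formulations
#'
#' A coupled N-gene S-system has `2N(N+1)` free parameters; each decoupled
#' per-gene sub-problem has `2(N+1)`.
#'
#' @param n_genes Number of genes, `>= 1`.
#' @return A one-row tibble with columns `coupled_total` and `per_gene`.
#' @export
#' @examples
#' parameter_counts(25)
parameter_counts <- function(n_genes) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 1 ||
      n_genes != round(n_genes)) {
    abort("n_genes must be a single integer >= 1", class = "igapso_argument_error")
  }
  n <- as.numeric(n_genes)
  tibble::tibble(coupled_total = 2 * n * (n + 1), per_gene = 2 * (n + 1))
}

#' Extract one gene's decoupled parameter vector
#'
#' Returns the per-gene search vector `(alpha_i, g_i1..g_iN, beta_i,
#' h_i1..h_iN)` of length `2(N+1)` -- the particle position space of the
#' optimizer.
#'
#' @param model An `s_system`.
#' @param gene Gene index (1-based) or name.
#' @return Numeric vector of length `2(N+1)`.
#' @export
gene_parameters <- function(model, gene) {
  i <- resolve_gene(model$gene_names, gene)
  c(model$alpha[i], model$g[i, ], model$beta[i], model$h[i, ])
}

#' Assemble per-gene parameter vectors into one model
#'
#' The inverse of [gene_parameters()]: combines `N` decoupled solutions
#' (gene `i`'s vector in position `i`) into a full `s_system`.
#'
#' @param params A list of `N` numeric vectors, each of length `2(N+1)`.
#' @param gene_names Optional gene labels.
#' @return An `s_system`.
#' @export
assemble_model <- function(params, gene_names = NULL) {
  n <- length(params)
  d <- 2 * (n + 1)
  if (!all(vapply(params, length, 0L) == d)) {
    abort("each parameter vector must have length 2(N+1)",
          class = "igapso_dimension_error")
  }
  mat <- do.call(rbind, params)
  s_system(alpha = mat[, 1], beta = mat[, n + 2],
           g = mat[, 2:(n + 1), drop = FALSE],
           h = mat[, (n + 3):d, drop = FALSE],
           gene_names = gene_names)
}

resolve_gene <- function(gene_names, gene) {
  if (is.character(gene)) {
    i <- match(gene, gene_names)
    if (is.na(i)) abort(paste0("unknown gene: ", gene),
                        class = "igapso_argument_error")
    return(i)
  }
  i <- as.integer(gene)
  if (is.na(i) || i < 1 || i > length(gene_names)) {
    abort("gene index out of range", class = "igapso_argument_error")
  }
  i
}

# ---- expression datasets ------------------------------------------------

# A dataset is a tibble whose first column is `time` (strictly increasing)
# and whose remaining columns are strictly positive gene concentrations.

check_dataset <- function(data, arg = "data") {
  if (!is.data.frame(data) || ncol(data) < 2) {
    abort(paste0(arg, " must be a data frame with a time column and at least one gene"),
          class = "igapso_argument_error")
  }
  times <- data[[1]]
  if (any(diff(times) <= 0) || nrow(data) < 2) {
    abort("times must be strictly increasing with T >= 2",
          class = "igapso_domain_error")
  }
  vals <- as.matrix(data[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0)) {
    abort("all concentrations must be positive and finite",
          class = "igapso_domain_error")
  }
  invisible(data)
}

dataset_times <- function(data) as.numeric(data[[1]])

dataset_matrix <- function(data) {
  m <- as.matrix(data[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

new_dataset <- function(times, values, gene_names) {
  colnames(values) <- gene_names
  dplyr::bind_cols(tibble::tibble(time = as.numeric(times)),
                   tibble::as_tibble(values))
}

# ---- simulation ---------------------------------------------------------

#' Simulate the coupled S-system
#'
#' Integrates all `N` equations jointly with fixed-step classical RK4
#' (`substeps` internal steps per observed interval). States are floored at
#' `eps` after every substep so negative kinetic orders remain defined.
#'
#' @param model An `s_system`.
#' @param x0 Positive initial concentrations, length `N`.
#' @param times Strictly increasing vector of output times.
#' @param substeps RK4 substeps per interval (default 10).
#' @param eps State floor.
#' @param cap Divergence cap: any state above it aborts integration with an
#'   error of class `igapso_divergence`.
#' @return A tibble with a `time` column and one column per gene.
#' @export
simulate_coupled <- function(model, x0, times, substeps = 10,
                             eps = STATE_FLOOR, cap = STATE_CAP) {
  stopifnot(inherits(model, "s_system"))
  if (length(x0) != n_genes(model) || any(x0 <= 0)) {
    abort("x0 must be positive with one entry per gene",
          class = "igapso_argument_error")
  }
  if (any(diff(times) <= 0)) {
    abort("times must be strictly increasing", class = "igapso_argument_error")
  }
  out <- cxx_rk4_coupled(model$alpha, model$beta, model$g, model$h,
                         as.numeric(x0), as.numeric(times),
                         as.integer(substeps), eps, cap)
  if (isTRUE(attr(out, "diverged"))) {
    abort("trajectory diverged beyond the state cap",
          class = "igapso_divergence")
  }
  attr(out, "diverged") <- NULL
  new_dataset(times, out, model$gene_names)
}

#' Simulate one gene's decoupled ODE against observed profiles
#'
#' Integrates gene `gene`'s rate equation alone, substituting the observed
#' (linearly interpolated) profiles of all other genes, starting from the
#' observed initial value. This is the forward model the optimizer fits.
#'
#' @param params Length-`2(N+1)` parameter vector, see [gene_parameters()].
#' @param data Expression dataset (time column plus gene columns).
#' @param gene Gene index or name.
#' @inheritParams simulate_coupled
#' @return Numeric vector of predicted concentrations at the dataset's times.
#' @export
simulate_decoupled_gene <- function(params, data, gene, substeps = 10,
                                    eps = STATE_FLOOR, cap = STATE_CAP) {
  check_dataset(data)
  n <- n_genes(data)
  if (length(params) != 2 * (n + 1)) {
    abort("params must have length 2(N+1) matching the dataset",
          class = "igapso_dimension_error")
  }
  i <- resolve_gene(colnames(data)[-1], gene)
  out <- cxx_decoupled_profile(as.numeric(params), i - 1L,
                               dataset_times(data), dataset_matrix(data),
                               as.integer(substeps), eps, cap)
  if (isTRUE(attr(out, "diverged"))) {
    abort("decoupled trajectory diverged beyond the state cap",
          class = "igapso_divergence")
  }
  as.numeric(out)
}

#' Sum of squared relative errors between predicted and desired profiles
#'
#' The optimizer's objective for one gene: `sum_t ((pred_t - des_t)/des_t)^2`
#' over the `T` time points (a sum, not a mean; set `normalize = TRUE` to
#' divide by `T`). Non-finite predictions return `penalty` so ranking stays
#' total.
#'
#' @param predicted,desired Equal-length numeric profiles; `desired` must be
#'   strictly positive.
#' @param normalize Divide by `T`? Default `FALSE`.
#' @param penalty Value returned for non-finite predictions.
#' @return Non-negative scalar.
#' @export
#' @examples
#' fitness_mse(rep(3, 4), rep(2, 4)) # 4 * ((3-2)/2)^2 = 1
fitness_mse <- function(predicted, desired, normalize = FALSE,
                        penalty = PENALTY_FITNESS) {
  if (length(predicted) != length(desired)) {
    abort("predicted and desired must have equal length",
          class = "igapso_dimension_error")
  }
  if (any(!is.finite(desired)) || any(desired <= 0)) {
    abort("desired values must be positive and finite",
          class = "igapso_domain_error")
  }
  if (any(!is.finite(predicted))) return(penalty)
  val <- sum(((predicted - desired) / desired)^2)
  if (!is.finite(val)) return(penalty)
  if (normalize) val / length(desired) else val
}

# decoupled fitness of a whole population (rows of `positions`) for one gene
fitness_batch <- function(positions, data, gene0, substeps = 10,
                          eps = STATE_FLOOR, cap = STATE_CAP,
                          penalty = PENALTY_FITNESS) {
  cxx_fitness_batch(positions, as.integer(gene0), dataset_times(data),
                    dataset_matrix(data), as.integer(substeps), eps, cap,
                    penalty)
}

# ---- tidiers ------------------------------------------------------------

#' Tidy an S-system into a long parameter table
#'
#' @param x An `s_system`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `parameter` (`alpha`, `beta`, `g`,
#'   `h`), `regulator` (`NA` for rate constants), and `value`.
#' @export
tidy.s_system <- function(x, ...) {
  n <- n_genes(x)
  gn <- x$gene_names
  rates <- tibble::tibble(
    gene = rep(gn, 2),
    parameter = rep(c("alpha", "beta"), each = n),
    regulator = NA_character_,
    value = c(x$alpha, x$beta)
  )
  orders <- tibble::tibble(
    gene = rep(rep(gn, each = n), 2),
    parameter = rep(c("g", "h"), each = n * n),
    regulator = rep(rep(gn, times = n), 2),
    value = c(t(x$g), t(x$h))
  )
  dplyr::bind_rows(rates, orders)
}

#' One-row summary of an S-system
#'
#' @param x An `s_system`.
#' @param ... Unused.
#' @return Tibble with gene count, parameter count, and number of nonzero
#'   off-diagonal regulatory entries.
#' @export
glance.s_system <- function(x, ...) {
  n <- n_genes(x)
  off <- !diag(n)
  tibble::tibble(
    n_genes = n,
    n_parameters = 2 * n * (n + 1),
    n_edges = sum((x$g != 0 | x$h != 0) & off),
    mean_in_degree = sum((x$g != 0) & off, (x$h != 0) & off) / n
  )
}
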