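# Whole-network inference: run the optimizer on every decoupled gene
# sub-problem and assemble the per-gene solutions into one S-system (the
# direct assembly strategy).

#' Infer an S-system gene network from time-series data
#'
#' Fits each gene's `2(N+1)` decoupled parameters independently with the
#' (island-model) hybrid GA-PSO and assembles the solutions into a full
#' model. Per-gene fitness is the sum of squared relative errors of the
#' decoupled re-simulation against the data.
#'
#' @param data Expression dataset: first column `time`, then positive gene
#'   concentrations.
#' @param cfg A [gapso_config()].
#' @param island_cfg An [island_config()], or `NULL` for a single swarm per
#'   gene.
#' @param genes Genes to fit (indices or names; default all).
#' @param workers Fork-pool size for the map phase.
#' @param spill_dir Optional directory for particle-record spill files.
#' @return An `igapso_fit`: the assembled `model`, a `per_gene` tibble
#'   (gene, fitness, r_squared of the decoupled profile), per-island
#'   `traces`, and the configurations used.
#' @export
#' @examples
#' \donttest{
#' bench <- generate_benchmark(benchmark_spec(3, noise_sd = 0, seed = 7))
#' cfg <- gapso_config(pop_size = 100, max_iterations = 30, seed = 7)
#' fit <- infer_network(bench$datasets[[1]], cfg)
#' glance(fit)
#' }
infer_network <- function(data, cfg = gapso_config(), island_cfg = NULL,
                          genes = NULL, workers = 1, spill_dir = NULL) {
  check_dataset(data)
  gene_names <- colnames(data)[-1]
  if (is.null(genes)) genes <- seq_along(gene_names)
  gis <- vapply(genes, function(g) resolve_gene(gene_names, g), 0L)
  runs <- lapply(gis, function(gi) {
    run_core(data, gi, cfg, island_cfg = island_cfg, workers = workers,
             spill_dir = spill_dir)
  })
  params <- lapply(runs, `[[`, "par")
  model <- if (length(gis) == length(gene_names)) {
    assemble_model(params, gene_names = gene_names)
  } else NULL
  per_gene <- purrr::map2_dfr(runs, params, function(run, par) {
    pred <- tryCatch(
      simulate_decoupled_gene(par, data, run$gene, substeps = cfg$substeps),
      igapso_divergence = function(e) rep(NA_real_, nrow(data))
    )
    obs <- data[[run$gene + 1]]
    r2 <- if (anyNA(pred) || stats::sd(pred) == 0) 0 else cor(obs, pred)^2
    tibble::tibble(gene = run$gene_name, fitness = run$fitness,
                   r_squared = r2)
  })
  traces <- purrr::map_dfr(runs, function(run) {
    dplyr::mutate(run$trace, gene = run$gene_name, .before = 1)
  })
  structure(
    list(model = model, params = setNames(params, gene_names[gis]),
         per_gene = per_gene, avg_fitness = mean(per_gene$fitness),
         traces = traces, config = cfg, island_config = island_cfg,
         data = data, seed = cfg$seed),
    class = "igapso_fit"
  )
}

#' @export
print.igapso_fit <- function(x, ...) {
  cat("<igapso_fit> ", nrow(x$per_gene), " gene sub-problems\n", sep = "")
  cat("  average fitness per gene: ", format(x$avg_fitness, digits = 6),
      "\n", sep = "")
  cat("  median  fitness per gene: ",
      format(median(x$per_gene$fitness), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Per-gene results of a network fit
#'
#' @param x An `igapso_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted gene: `gene`, final decoupled
#'   `fitness`, and `r_squared` of the re-simulated profile.
#' @export
tidy.igapso_fit <- function(x, ...) x$per_gene

#' One-row summary of a network fit
#'
#' @param x An `igapso_fit`.
#' @param ... Unused.
#' @return Tibble with gene count, mean/median per-gene fitness, pooled
#'   scatter R-squared of the decoupled profiles, and the seed.
#' @export
glance.igapso_fit <- function(x, ...) {
  sm <- tryCatch(
    scatter_metrics(predict_profiles(x), x$data[, c("time", x$per_gene$gene)]),
    error = function(e) NULL
  )
  tibble::tibble(
    n_genes = nrow(x$per_gene),
    mean_fitness = mean(x$per_gene$fitness),
    median_fitness = median(x$per_gene$fitness),
    pooled_r_squared = if (is.null(sm)) NA_real_ else sm$pooled_r_squared,
    seed = x$seed
  )
}

#' Re-simulate expression profiles from a fitted or known model
#'
#' `type = "decoupled"` integrates each gene's equation against the observed
#' profiles of the other genes (the quantity the optimizer fitted);
#' `type = "coupled"` integrates the assembled model jointly from the
#' observed initial state, a stricter end-to-end check.
#'
#' @param object An `igapso_fit` or [s_system()].
#' @param data Expression dataset (defaults to the fit's training data).
#' @param type `"decoupled"` or `"coupled"`.
#' @param substeps RK4 substeps per interval.
#' @return An expression-dataset tibble of predicted profiles.
#' @export
predict_profiles <- function(object, data = NULL,
                             type = c("decoupled", "coupled"), substeps = 10) {
  type <- match.arg(type)
  if (inherits(object, "igapso_fit")) {
    if (is.null(data)) data <- object$data
    params <- object$params
    model <- object$model
  } else {
    stopifnot(inherits(object, "s_system"))
    if (is.null(data)) abort("data is required", class = "igapso_argument_error")
    params <- setNames(
      lapply(seq_len(n_genes(object)), gene_parameters, model = object),
      object$gene_names
    )
    model <- object
  }
  check_dataset(data)
  if (type == "coupled") {
    if (is.null(model)) {
      abort("coupled prediction needs a complete model",
            class = "igapso_argument_error")
    }
    x0 <- as.numeric(dataset_matrix(data)[1, ])
    return(simulate_coupled(model, x0, dataset_times(data),
                            substeps = substeps))
  }
  preds <- lapply(names(params), function(gn) {
    simulate_decoupled_gene(params[[gn]], data, gn, substeps = substeps)
  })
  new_dataset(dataset_times(data), do.call(cbind, preds), names(params))
}
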