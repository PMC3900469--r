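# Fit-quality metrics: inferred-vs-actual scatter statistics and run reports.

#' Scatter metrics between inferred and actual profiles
#'
#' Pools the `T x N` (time point, gene) pairs of two datasets and reports the
#' squared Pearson correlation between actual and inferred concentrations --
#' the statistic summarized by inferred-vs-actual scatter plots -- plus
#' per-gene values. A profile with zero variance has undefined correlation
#' and is reported as 0 with a warning.
#'
#' @param inferred,actual Expression-dataset tibbles of matching shape.
#' @return A `scatter_metrics` list: `per_gene` tibble (gene, r_squared),
#'   `pooled_r_squared`, and `n_dots = T * N`.
#' @export
#' @examples
#' d <- generate_benchmark(benchmark_spec(3, noise_sd = 0))$datasets[[1]]
#' scatter_metrics(d, d)$pooled_r_squared # 1
scatter_metrics <- function(inferred, actual) {
  check_dataset(actual)
  if (!identical(dim(inferred), dim(actual))) {
    abort("inferred and actual datasets must have matching shape",
          class = "igapso_dimension_error")
  }
  mi <- dataset_matrix(inferred)
  ma <- dataset_matrix(actual)
  safe_r2 <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warn("zero-variance profile; R-squared undefined, reporting 0")
      return(0)
    }
    cor(a, b)^2
  }
  per_gene <- tibble::tibble(
    gene = colnames(actual)[-1],
    r_squared = vapply(seq_len(ncol(ma)), function(j) safe_r2(ma[, j], mi[, j]), 0)
  )
  structure(
    list(per_gene = per_gene,
         pooled_r_squared = safe_r2(as.vector(ma), as.vector(mi)),
         n_dots = length(ma)),
    class = "scatter_metrics"
  )
}

#' @export
print.scatter_metrics <- function(x, ...) {
  cat("<scatter_metrics> ", x$n_dots, " dots, pooled R-squared ",
      format(x$pooled_r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Assemble and write a run report
#'
#' A TSV with one row per gene (fitness and R-squared) plus a human-readable
#' summary carrying the seed and configuration values needed to reproduce the
#' run.
#'
#' @param fit An `igapso_fit`.
#' @param path Output TSV path; a `.summary.txt` sibling is written next to
#'   it.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "igapso_fit"))
  readr::write_tsv(fit$per_gene, path)
  cfg <- fit$config
  summary_path <- sub("(\\.tsv)?$", ".summary.txt", path)[1]
  lines <- c(
    "igapso run report",
    paste0("seed: ", fit$seed),
    paste0("pop_size: ", cfg$pop_size, "  iterations: ", cfg$max_iterations,
           "  p_elite: ", cfg$p_elite, "  r_random: ", cfg$r_random),
    if (!is.null(fit$island_config)) {
      paste0("islands: ", fit$island_config$n_islands, "  migration_interval: ",
             fit$island_config$migration_interval)
    } else "islands: 1 (single swarm)",
    paste0("average fitness per gene: ", format(fit$avg_fitness, digits = 8)),
    paste0("median fitness per gene: ",
           format(median(fit$per_gene$fitness), digits = 8))
  )
  writeLines(lines, summary_path)
  invisible(path)
}
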