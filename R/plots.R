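# ggplot2 visualisations.

#' Plot best-so-far fitness traces
#'
#' One line per island (and per gene for a full network fit), on a log10
#' fitness scale.
#'
#' @param x A `gapso_run` or `igapso_fit`.
#' @return A ggplot object.
#' @export
plot_fitness_trace <- function(x) {
  tr <- if (inherits(x, "igapso_fit")) x$traces else
    dplyr::mutate(x$trace, gene = x$gene_name, .before = 1)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$gbest,
                                   colour = factor(.data$island))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = "iteration", y = "best fitness (log scale)",
                  colour = "island") +
    ggplot2::theme_minimal()
}

#' Inferred-versus-actual concentration scatter plot
#'
#' One dot per (time point, gene) pair; the diagonal marks a perfect fit.
#'
#' @param inferred,actual Expression-dataset tibbles of matching shape.
#' @return A ggplot object.
#' @export
plot_scatter <- function(inferred, actual) {
  df <- tibble::tibble(
    actual = as.vector(dataset_matrix(actual)),
    inferred = as.vector(dataset_matrix(inferred))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$inferred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "actual concentration", y = "inferred concentration") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gapso_run <- function(object, ...) plot_fitness_trace(object)

#' @export
autoplot.igapso_fit <- function(object, type = c("trace", "scatter"), ...) {
  type <- match.arg(type)
  if (type == "trace") return(plot_fitness_trace(object))
  plot_scatter(predict_profiles(object),
               object$data[, c("time", object$per_gene$gene)])
}

#' Plot expression time courses
#'
#' @param data Expression-dataset tibble.
#' @return A ggplot object with one line per gene.
#' @export
plot_timeseries <- function(data) {
  check_dataset(data)
  long <- tidyr::pivot_longer(data, -"time", names_to = "gene",
                              values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$concentration,
                                     colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
}
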