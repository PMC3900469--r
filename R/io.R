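# Readers and writers.
#
# Time series travel as TSV/CSV with a leading `time` column and one column
# per gene; models as JSON documents with named alpha/beta/g/h blocks. Both
# round-trip exactly (numbers written at 17 significant digits / full JSON
# precision).

#' Read a time-series expression table
#'
#' The delimiter (tab or comma) is sniffed from the header line. The first
#' column must be a strictly increasing `time`; all remaining cells must be
#' positive numbers.
#'
#' @param path Path to a TSV/CSV file.
#' @return An expression-dataset tibble.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "igapso_argument_error")
  }
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  vals <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad) > 0 || anyNA(raw[[j]])) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(raw[[j]]))[1]
      abort(paste0("non-numeric cell at row ", row, ", column ",
                   names(raw)[j]), class = "igapso_parse_error")
    }
    vals[, j] <- v
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- names(raw)
  names(out)[1] <- "time"
  check_dataset(out)
  out
}

#' Write a time-series expression table
#'
#' @param data Expression-dataset tibble.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated. Numbers are written at 17 significant digits, so
#'   write-then-read is exact.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  check_dataset(data)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- cbind(dataset_times(data), dataset_matrix(data))
  lines <- c(paste(names(data), collapse = sep),
             apply(m, 1, function(r) paste(fmt17(r), collapse = sep)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an S-system model document
#'
#' JSON with named blocks `alpha`, `beta`, `g`, `h` (row-major matrices) and
#' `gene_names`; numeric values keep full precision so the round trip is
#' exact.
#'
#' @param model An [s_system()].
#' @param path File path.
#' @return `read_model()` returns an [s_system()]; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "s_system"))
  doc <- list(gene_names = model$gene_names, alpha = model$alpha,
              beta = model$beta, g = model$g, h = model$h)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  s_system(doc$alpha, doc$beta, doc$g, doc$h, gene_names = doc$gene_names)
}

#' Export per-island fitness traces as TSV
#'
#' @param run A `gapso_run` or `igapso_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path) {
  tr <- if (inherits(run, "igapso_fit")) run$traces else run$trace
  readr::write_tsv(tr, path)
  invisible(path)
}
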