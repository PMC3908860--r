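## Plain-text serialization: traces as CSV, statistics as JSON, regime
## grids as TSV.  Floating point is written with 12 significant digits,
## enough to round-trip the bifurcation anchors.

fmt12 <- function(x) formatC(x, digits = 12, format = "g")

#' Write / read a trace as CSV
#'
#' @param trace a trace tibble (single-cell columns `time`, `V`, `h_Na`,
#'   `m_K2`, `m_h`, or the long network layout with a `segment` column).
#' @param path file path.
#' @return `read_trace_csv` returns a tibble; values round-trip to
#'   12 significant digits.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(lapply(trace, function(col)
    if (is.numeric(col)) fmt12(col) else col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Write / read statistics as JSON
#'
#' Serializes a [temporal_stats()] object (or any list of scalars and
#' data frames) to JSON and back.
#'
#' @param stats object to serialize.
#' @param path file path.
#' @return `read_stats_json` returns the list; a serialized
#'   `temporal_stats` regains its class.
#' @export
write_stats_json <- function(stats, path) {
  x <- unclass(stats)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_stats_json
#' @export
read_stats_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("cycles", "burst_duration", "duty") %in% names(x))) {
    x$cycles <- tibble::as_tibble(x$cycles)
    class(x) <- "temporal_stats"
  }
  x
}

#' Write / read a regime grid as TSV
#'
#' @param grid a [map_regimes()] tibble (`theta_K2`, `theta_h`, `label`,
#'   `duty`); silent cells have `NA` duty, written as `NA`.
#' @param path file path.
#' @return `read_grid_tsv` returns the tibble.
#' @export
write_grid_tsv <- function(grid, path) {
  df <- data.frame(theta_K2 = fmt12(grid$theta_K2),
                   theta_h = fmt12(grid$theta_h),
                   label = grid$label,
                   duty = ifelse(is.na(grid$duty), "NA", fmt12(grid$duty)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "NA",
                          colClasses = c("numeric", "numeric",
                                         "character", "numeric"))
  tibble::as_tibble(df)
}
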