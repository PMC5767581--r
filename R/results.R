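#' Result tables
#'
#' Coherence spectra, band topographies and test reports are serialised as a
#' flat table with the fixed column order `key`, `frequency`, `value`,
#' `units`. `frequency` may hold a numeric frequency in Hz or a band label
#' such as `"15-30"`.
#'
#' @param key,frequency,value,units Column vectors (recycled to a common
#'   length).
#' @return A `cmc_results` tibble.
#' @export
result_table <- function(key = character(), frequency = numeric(),
                         value = numeric(), units = character()) {
  out <- tibble::tibble(key = key, frequency = frequency, value = value,
                        units = units)
  validate_result_table(out)
  class(out) <- c("cmc_results", class(out))
  out
}

validate_result_table <- function(tab) {
  stopifnot(all(c("key", "frequency", "value", "units") %in% names(tab)))
  f <- suppressWarnings(as.numeric(tab$frequency))
  if (any(f < 0, na.rm = TRUE)) {
    stop("result error: negative frequency", call. = FALSE)
  }
  invisible(tab)
}

#' Write a result table to TSV or JSON
#'
#' TSV output has a deterministic column order (`key`, `frequency`, `value`,
#' `units`); JSON preserves full double precision so that values re-parse
#' bit-exactly.
#'
#' @param table A data frame with the [result_table()] columns.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("tsv", "json")) {
  if (length(format) == 1 && !format %in% c("tsv", "json")) {
    stop("usage error: unknown format '", format, "' (use \"tsv\" or \"json\")",
         call. = FALSE)
  }
  format <- match.arg(format)
  validate_result_table(table)
  table <- table[, c("key", "frequency", "value", "units")]
  if (format == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back a result table
#'
#' @param path Path written by [write_results()].
#' @param format `"tsv"` or `"json"`.
#' @return A tibble.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                        colClasses = c("character", "character",
                                                       "numeric", "character")))
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
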