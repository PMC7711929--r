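#' Read a count series from a one-column CSV/TSV file
#'
#' Accepts a single column of non-negative integers, with or without a
#' header line (conventionally \code{count}).
#'
#' @param path file path.
#' @return integer vector.
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(
    strsplit(first, "[,\t;]")[[1]][1])))
  x <- utils::read.table(path, header = has_header,
                         sep = if (grepl("\t", first)) "\t" else ",")[[1]]
  as.integer(check_counts(x))
}

#' Write a count series to a one-column CSV file
#'
#' @param y count series.
#' @param path file path.
#' @export
write_counts <- function(y, path) {
  check_counts(y)
  utils::write.table(data.frame(count = as.integer(y)), path,
                     sep = ",", row.names = FALSE, quote = FALSE)
}
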