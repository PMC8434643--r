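#' Read and write calibration tables
#'
#' Calibration tables are 3-column tab-delimited text with a header:
#' `pressure` (kg cm^-2), `resistance_kohm`, `conductance` (mS).
#'
#' @param path File path.
#' @return `read_calibration_table()` returns a data frame;
#'   `write_calibration_table()` returns `path` invisibly.
#' @export
read_calibration_table <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = TRUE)
  need <- c("pressure", "resistance_kohm", "conductance")
  if (!all(need %in% names(tab))) {
    stop_domain("calibration table must have columns: ",
                paste(need, collapse = ", "))
  }
  if (is.unsorted(tab$pressure, strictly = TRUE)) {
    stop_domain("calibration pressures must be strictly increasing")
  }
  tab[need]
}

#' @rdname read_calibration_table
#' @param table A calibration data frame.
#' @export
write_calibration_table <- function(table, path) {
  need <- c("pressure", "resistance_kohm", "conductance")
  stopifnot(all(need %in% names(table)))
  write.table(table[need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a calibration curve as JSON
#'
#' A [calibration_curve()] is serialized as a JSON object `{"a": ..., "b": ...}`.
#'
#' @param path File path.
#' @return `read_calibration_curve()` returns a [calibration_curve()];
#'   `write_calibration_curve()` returns `path` invisibly.
#' @export
read_calibration_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("a", "b") %in% names(obj))) {
    stop_domain("curve JSON must contain fields 'a' and 'b'")
  }
  calibration_curve(a = obj$a, b = obj$b)
}

#' @rdname read_calibration_curve
#' @param curve A [calibration_curve()].
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(list(a = curve$a, b = curve$b), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
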