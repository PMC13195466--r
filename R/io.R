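#' Read/write burn events and observations as CSV
#'
#' ISO-8601 dates; columns exactly as the corresponding table fields.
#' @param x Event or observation table.
#' @param path CSV path.
#' @export
write_events_csv <- function(x, path) {
  x$date <- format(as.Date(x$date))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x
}

#' Serialize a calibration model to JSON
#' @param model A `pf_calibration`.
#' @param path JSON path.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "pf_calibration"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "pf_calibration")
}
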