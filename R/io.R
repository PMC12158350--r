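#' Read a batch of vectors from CSV or JSON
#'
#' The batch format has columns `r1`, `theta1` and optionally `r2`,
#' `theta2`, `heading`. CSV is comma-separated with a mandatory header
#' row, dot decimals, UTF-8; JSON is an array of records with the same
#' fields. Angles may be supplied in degrees or radians and are
#' normalized to `[0, 2*pi)` radians on read. Malformed rows
#' (non-numeric cells, negative magnitudes, missing values) are
#' reported with their row numbers.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; inferred from the file extension
#'   by default.
#' @param angles Units of the angle columns in the file.
#' @return A data frame with normalized angle columns in radians.
#' @export
read_vectors <- function(path, format = c("auto", "csv", "json"),
                         angles = c("radians", "degrees")) {
  format <- match.arg(format)
  angles <- match.arg(angles)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("r1", "theta1")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- intersect(c("r1", "theta1", "r2", "theta2", "heading"),
                        names(df))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("column '%s' has non-numeric or missing values at row(s) %s",
                   col, paste(bad, collapse = ", ")))
    }
    df[[col]] <- v
  }
  for (col in intersect(c("r1", "r2"), names(df))) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative magnitude in column '%s' at row(s) %s",
                   col, paste(bad, collapse = ", ")))
    }
  }
  scale <- if (angles == "degrees") pi / 180 else 1
  for (col in intersect(c("theta1", "theta2", "heading"), names(df))) {
    df[[col]] <- normalize_angle(df[[col]] * scale)
  }
  df
}

#' Write a batch of vectors to CSV or JSON
#'
#' Inverse of [read_vectors()]; a write-then-read round trip is the
#' identity (angles stored in radians).
#'
#' @param df Data frame with the batch columns.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; inferred from the extension by
#'   default.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(df, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write an error report to disk
#'
#' Per-trial records as CSV plus a JSON summary block (aggregate
#' statistics, configuration and package version), matching the
#' reproducibility contract: a report can be regenerated bit-identically
#' from its logged configuration and seed.
#'
#' @param report An `error_report` from [run_experiment()].
#' @param prefix Output path prefix; writes `<prefix>_trials.csv` and
#'   `<prefix>_summary.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_error_report <- function(report, prefix) {
  stopifnot(inherits(report, "error_report"))
  csv_path <- paste0(prefix, "_trials.csv")
  json_path <- paste0(prefix, "_summary.json")
  utils::write.csv(report$trials, csv_path, row.names = FALSE, quote = FALSE)
  payload <- list(
    summary = report$summary,
    config = unclass(report$config),
    package_version = as.character(utils::packageVersion("ebnav")))
  jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(csv_path, json_path))
}
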