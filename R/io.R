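#' Read an indexed series from a delimited file
#'
#' Expects a header row and at least an integer index column and a numeric
#' value column. Rows whose value cell is empty or `NA` become missing
#' positions (absent indices); duplicate indices are rejected.
#'
#' @param path Path to a CSV/TSV file.
#' @param index_column,value_column Column names (or 1-based positions).
#' @param delimiter Field delimiter; `NULL` guesses from the file extension
#'   (`.tsv`/`.txt` => tab, otherwise comma).
#' @param reference Optional reference index, passed to [indexed_series()].
#' @return An [indexed_series()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("index,value", "0,100", "1,101", "2,", "3,103"), f)
#' read_series(f)  # position 2 is missing
#' @export
read_series <- function(path, index_column = 1L, value_column = 2L,
                        delimiter = NULL, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
      "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, colClasses = "character",
                          strip.white = TRUE)
  col <- function(spec) {
    if (is.numeric(spec)) {
      if (spec > ncol(df)) stop("column ", spec, " not in file", call. = FALSE)
      df[[spec]]
    } else {
      if (!spec %in% names(df)) {
        stop("column '", spec, "' not in file", call. = FALSE)
      }
      df[[spec]]
    }
  }
  idx_raw <- col(index_column)
  val_raw <- col(value_column)
  idx <- suppressWarnings(as.numeric(idx_raw))
  if (any(is.na(idx)) || any(idx != trunc(idx)) || any(idx < 0)) {
    stop("index column must contain non-negative integers", call. = FALSE)
  }
  keep <- !(is.na(val_raw) | val_raw == "" | toupper(val_raw) == "NA")
  val <- suppressWarnings(as.numeric(val_raw[keep]))
  if (any(is.na(val))) {
    stop("malformed numeric value(s): ",
         paste(utils::head(val_raw[keep][is.na(val)], 3), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("duplicate indices in input", call. = FALSE)
  }
  if (sum(keep) < 2L) {
    stop("need at least 2 present values", call. = FALSE)
  }
  indexed_series(idx[keep], val, reference = reference)
}

#' Write detection labels (and optionally the trace) to CSV
#'
#' Writes one row per grid position with columns `index`, `value` (empty for
#' missing positions) and `label`. Values are written at full double
#' precision so a write/read round trip is lossless. If `trace_path` is
#' given, the detection trace is written alongside as a CSV log, one row per
#' iteration.
#'
#' @param path Output CSV path.
#' @param labels An [outlier_labels()] frame (or an `outlier_detection`
#'   object, whose labels and trace are used).
#' @param trace Optional `detection_trace` data frame.
#' @param trace_path Optional path for the trace sidecar.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(path, labels, trace = NULL, trace_path = NULL) {
  if (inherits(labels, "outlier_detection")) {
    if (is.null(trace)) trace <- labels$trace
    labels <- labels$labels
  }
  stopifnot(inherits(labels, "outlier_labels"))
  df <- data.frame(
    index = labels$index,
    value = ifelse(is.na(labels$value), "",
                   sprintf("%.17g", labels$value)),
    label = as.character(labels$label)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(trace_path) && !is.null(trace)) {
    utils::write.csv(as.data.frame(trace), trace_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a label CSV written by [write_labels()]
#'
#' @param path Path to the label CSV.
#' @return An [outlier_labels()] frame.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character", "character"))
  val <- suppressWarnings(as.numeric(ifelse(df$value == "", NA, df$value)))
  outlier_labels(df$index, df$label, val)
}
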