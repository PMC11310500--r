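#' Build and validate a cohort metric table
#'
#' The metric table is a plain data.frame with columns \code{patient_id},
#' \code{organ}, \code{method}, \code{metric} and \code{value}, one row per
#' (patient, organ, method, metric). NaN marks an undefined metric.
#'
#' @param patient_id,organ,method,metric,value vectors of equal length (or a
#'   single data.frame passed as \code{patient_id}).
#' @return validated data.frame.
#' @export
metricTable <- function(patient_id, organ = NULL, method = NULL,
                        metric = NULL, value = NULL) {
  df <- if (is.data.frame(patient_id)) patient_id else
    data.frame(patient_id = as.character(patient_id),
               organ = as.character(organ), method = as.character(method),
               metric = as.character(metric), value = as.numeric(value),
               stringsAsFactors = FALSE)
  validateMetricTable(df)
  df
}

#' @rdname metricTable
#' @param table a candidate metric table.
#' @export
validateMetricTable <- function(table) {
  req <- c("patient_id", "organ", "method", "metric", "value")
  if (!all(req %in% names(table)))
    stop("metric table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(table$metric), metricNames("all"))
  if (length(bad))
    stop("unknown metric name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(table$patient_id, table$organ, table$method, table$metric,
               sep = "\r")
  if (anyDuplicated(key))
    stop("integrity error: duplicate (patient, organ, method, metric) records",
         call. = FALSE)
  invisible(TRUE)
}

#' Write / read a metric table as CSV
#'
#' NaN values are serialized as empty cells and read back as NaN; the
#' round-trip preserves all records.
#'
#' @param table a metric table (see [metricTable()]).
#' @param path CSV path.
#' @return \code{writeMetricTable}: the path invisibly;
#'   \code{readMetricTable}: the table.
#' @export
writeMetricTable <- function(table, path) {
  validateMetricTable(table)
  out <- table[, c("patient_id", "organ", "method", "metric", "value")]
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", na = "")
  invisible(path)
}

#' @rdname writeMetricTable
#' @export
readMetricTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       organ = "character",
                                       method = "character",
                                       metric = "character",
                                       value = "numeric"))
  df$value[is.na(df$value)] <- NaN
  validateMetricTable(df)
  df
}
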