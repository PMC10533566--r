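# CSV / JSON plumbing shared by the pipeline commands.
# Dialect: comma-separated, UTF-8, '.' decimal, mandatory header row.

#' Write / read a cohort table as CSV
#' @param cohort A cohort data frame.
#' @param path File path.
#' @rdname cohort_io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("id", "group")
  miss <- setdiff(need, names(coh))
  if (length(miss)) stop("cohort CSV lacks columns: ", paste(miss, collapse = ", "))
  class(coh) <- c("salisense_cohort", "data.frame")
  coh
}

#' Write / read a response matrix as CSV (id column + S1_R..S12_B)
#' @param responses n x 36 matrix with row-name ids.
#' @param path File path.
#' @rdname response_io
#' @export
write_response_csv <- function(responses, path) {
  m <- unclass(as.matrix(responses))
  df <- data.frame(id = rownames(m), m, row.names = NULL,
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname response_io
#' @export
read_response_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!"id" %in% names(df)) stop("response CSV lacks an 'id' column")
  feat <- setdiff(names(df), "id")
  if (length(feat) != 36L) {
    stop("response CSV must have 36 feature columns, found ", length(feat))
  }
  m <- as.matrix(df[, feat])
  rownames(m) <- df$id
  if (anyNA(m)) stop("response CSV contains missing values")
  if (any(m < 0 | m > 255)) stop("response features must lie in [0, 255]")
  class(m) <- c("salisense_responses", class(m))
  m
}

# Recursively replace non-finite numerics with NULL + reason, so every
# numeric in a report JSON is finite or explicitly null.
finite_or_null <- function(x) {
  if (is.list(x)) return(lapply(x, finite_or_null))
  if (is.numeric(x) && length(x) == 1L && !is.finite(x)) {
    return(list(value = NULL, reason = paste("non-finite:", format(x))))
  }
  x
}

write_report_json <- function(report, path) {
  jsonlite::write_json(finite_or_null(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
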