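# Reader/writer for the tab-delimited STO/MOT time-series dialect used by
# biomechanics tooling: a small key=value header terminated by "endheader",
# one row of column labels (time first), then a numeric matrix.

#' Read an STO/MOT time-series file
#'
#' Parses the tab-delimited storage dialect common in musculoskeletal
#' simulation tooling. The header must declare `nRows` and `nColumns` and end
#' with `endheader`; the first column must be strictly increasing time. When
#' the header declares `inDegrees=yes`, all non-time columns are converted to
#' radians on load.
#'
#' @param path file path
#' @return a list of class `sto_table` with elements `name`, `labels`
#'   (character, first is `"time"`), `data` (numeric matrix, one column per
#'   label) and `in_degrees_source` (logical; data are always radians after
#'   load).
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0) stop("STO format error: missing 'endheader' in ", path)
  end <- end[1]
  header <- lines[seq_len(end - 1)]
  kv <- list()
  for (ln in header) {
    if (grepl("=", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
    }
  }
  labels <- strsplit(lines[end + 1], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(end + 1)]
  body <- body[nzchar(trimws(body))]
  data <- matrix(NA_real_, nrow = length(body), ncol = length(labels))
  for (i in seq_along(body)) {
    vals <- as.numeric(strsplit(body[i], "\t", fixed = TRUE)[[1]])
    if (length(vals) != length(labels))
      stop("STO format error at line ", end + 1 + i, ": expected ",
           length(labels), " columns, found ", length(vals))
    data[i, ] <- vals
  }
  colnames(data) <- labels
  if (!is.null(kv$nRows) && as.integer(kv$nRows) != nrow(data))
    stop("STO format error: header declares nRows=", kv$nRows,
         " but file has ", nrow(data), " data rows (line ", end + 2, ")")
  if (!is.null(kv$nColumns) && as.integer(kv$nColumns) != ncol(data))
    stop("STO format error: header declares nColumns=", kv$nColumns,
         " but file has ", ncol(data), " columns")
  if (is.unsorted(data[, 1], strictly = TRUE))
    stop("STO format error: time column is not strictly increasing in ", path)
  in_deg <- identical(tolower(kv$inDegrees %||% "no"), "yes")
  if (in_deg && ncol(data) > 1)
    data[, -1] <- data[, -1] * pi / 180
  structure(list(name = kv$name %||% basename(path), labels = labels,
                 data = data, in_degrees_source = in_deg),
            class = "sto_table")
}

#' Write an STO/MOT time-series file
#'
#' Numeric values are written with 17 significant digits so that a
#' write-then-read round trip is bitwise lossless for doubles.
#'
#' @param table an `sto_table`, or a numeric matrix with a `time` first column
#' @param path output path
#' @param name storage name recorded in the header
#' @return `path`, invisibly
#' @export
write_sto <- function(table, path, name = NULL) {
  if (is.matrix(table)) {
    table <- list(name = name %||% "table",
                  labels = colnames(table) %||% c("time", paste0("col", seq_len(ncol(table) - 1))),
                  data = table)
  }
  data <- table$data
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("name=", name %||% table$name),
    paste0("nRows=", nrow(data)),
    paste0("nColumns=", ncol(data)),
    "inDegrees=no",
    "version=1",
    "endheader",
    paste(table$labels, collapse = "\t")), con)
  body <- apply(data, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
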