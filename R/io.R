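#' Write traces to a delimited text file
#'
#' Writes a multi-channel trace table in the package's interchange format,
#' modelled on acquisition-software ASCII exports: a `#`-prefixed header
#' block of `key: value` metadata lines, one line of tab-separated column
#' names (first column `time`), then tab-separated data rows. Numbers are
#' written with a locale-independent decimal point at full double
#' precision, so that write-read round-trips are exact on values.
#'
#' @param trace A tibble whose first column is `time` \[s\] (strictly
#'   increasing, uniform step) followed by named channel columns.
#' @param path Output file path.
#' @param header Named list of metadata to record (`fs` is added
#'   automatically).
#' @return `path`, invisibly.
#' @export
write_traces <- function(trace, path, header = list()) {
  stopifnot(is.data.frame(trace), names(trace)[1] == "time")
  fs <- trace_fs(trace)
  header <- c(list(format = "plethysim-trace-1", fs = fs), header)
  lines <- c(
    sprintf("# %s: %s", names(header),
            vapply(header, function(v) paste(format(v, digits = 15),
                                             collapse = " "), character(1))),
    paste(names(trace), collapse = "\t"))
  body <- do.call(paste, c(lapply(trace, function(col) {
    sprintf("%.17g", as.numeric(col))
  }), sep = "\t"))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read traces from a delimited text file
#'
#' Counterpart of [write_traces()]. Unknown header keys are preserved, and
#' extra channel columns are read as-is. The time column is validated to
#' be strictly increasing with a uniform step; a gap or a malformed row
#' raises an error naming the offending line.
#'
#' @param path File path.
#' @return A tibble with `time` plus the channel columns; the parsed header
#'   is attached as attribute `"header"`.
#' @export
read_traces <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  hdr_lines <- lines[is_comment]
  header <- list()
  for (h in sub("^#\\s*", "", hdr_lines)) {
    m <- regmatches(h, regexec("^([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      header[[trimws(m[2])]] <- if (is.na(val)) m[3] else val
    }
  }
  data_lines <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_lines) < 2) stop("No data found in trace file.", call. = FALSE)
  cols <- strsplit(lines[data_lines[1]], "\t", fixed = TRUE)[[1]]
  body <- data_lines[-1]
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != length(cols))) {
    bad <- body[which(nc != length(cols))[1]]
    stop(sprintf("Malformed trace file: line %d has %d fields, expected %d.",
                 bad, nc[which(nc != length(cols))[1]], length(cols)),
         call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = length(cols), byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(mat, 1, anyNA))[1]
    stop(sprintf("Malformed trace file: non-numeric value on line %d.",
                 body[bad_row]), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- cols
  if (names(out)[1] != "time") {
    stop("Trace file must have `time` as its first column.", call. = FALSE)
  }
  dt <- diff(out$time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * stats::median(dt)) {
    bad <- which(abs(dt - stats::median(dt)) > 1e-9 * stats::median(dt))[1]
    stop(sprintf("Trace file time column is not uniform near line %d.",
                 body[bad + 1]), call. = FALSE)
  }
  if (!is.null(header$fs) &&
      abs(header$fs - 1 / stats::median(dt)) > 1e-6 * header$fs) {
    stop("Header `fs` is inconsistent with the time column.", call. = FALSE)
  }
  attr(out, "header") <- header
  out
}
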