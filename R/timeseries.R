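#' Construct a multivariate time-series set
#'
#' Container for one subject's T x N network time series. Rows are time
#' points, columns are named channels (networks); `TR` is the repetition time
#' in seconds (the sampling interval of the series).
#'
#' @param data Numeric matrix, T rows (time) by N columns (channels).
#' @param TR Repetition time in seconds (> 0).
#' @param channels Channel names; defaults to `colnames(data)`.
#' @param subject_id Subject identifier.
#' @param group Optional group label.
#' @return An object of class `"ts_set"`.
#' @export
time_series_set <- function(data, TR, channels = colnames(data),
                            subject_id = "subject", group = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric", call. = FALSE)
  if (is.null(channels)) stop("channel names are required", call. = FALSE)
  if (length(channels) != ncol(data))
    stop("number of channel names does not match number of columns", call. = FALSE)
  if (anyDuplicated(channels)) stop("channel names must be unique", call. = FALSE)
  if (ncol(data) < 2) stop("at least 2 channels are required", call. = FALSE)
  assert_scalar_num(TR, "TR", positive = TRUE)
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value at row %d, column '%s'",
                 bad[1, 1], channels[bad[1, 2]]), call. = FALSE)
  if (nrow(data) < 10)
    stop(sprintf("too few time points (T = %d); need at least 10", nrow(data)),
         call. = FALSE)
  dimnames(data) <- list(NULL, channels)
  structure(list(subject_id = subject_id, data = data,
                 channels = as.character(channels), TR = TR, group = group),
            class = "ts_set")
}

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf("<ts_set> subject '%s'%s: %d time points x %d channels, TR = %g s\n",
              x$subject_id,
              if (is.null(x$group)) "" else sprintf(" [%s]", x$group),
              nrow(x$data), ncol(x$data), x$TR))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Read a time-series table from delimited text
#'
#' Expects a tab-delimited file with a header row of channel names and one
#' numeric row per time point. Validation errors name the offending row and
#' column.
#'
#' @param path Path to the TSV file.
#' @param TR Repetition time in seconds (plain tables carry no time metadata,
#'   so it must be supplied).
#' @param subject_id Subject identifier; defaults to the file name stem.
#' @param group Optional group label.
#' @return A [time_series_set()] object.
#' @export
load_timeseries <- function(path, TR, subject_id = NULL, group = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1)
  if (!nzchar(header) || !grepl("[A-Za-z]", header))
    stop(sprintf("missing header row of channel names in %s", path), call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  channels <- colnames(tab)
  mat <- matrix(NA_real_, nrow(tab), ncol(tab))
  for (j in seq_along(channels)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      raw <- tab[[j]][bad[1]]
      what <- if (is.na(suppressWarnings(as.numeric(raw)))) "non-numeric cell"
              else "non-finite value"
      stop(sprintf("%s at row %d, column '%s' in %s", what, bad[1], channels[j], path),
           call. = FALSE)
    }
    mat[, j] <- v
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  time_series_set(mat, TR = TR, channels = channels,
                  subject_id = subject_id, group = group)
}

#' Write a time-series set to delimited text
#'
#' Deterministic writer: fixed 17-significant-digit float formatting, tab
#' separator, `\n` line endings, so identical objects produce byte-identical
#' files.
#'
#' @param x A [time_series_set()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "ts_set"))
  lines <- c(paste(x$channels, collapse = "\t"),
             apply(x$data, 1, function(r) paste(format_float(r), collapse = "\t")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
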