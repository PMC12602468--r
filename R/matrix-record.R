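#' Construct a labelled connectivity matrix record
#'
#' An N x N matrix of directed quantities with the project-wide orientation
#' convention: entry (i, j) is the influence of source channel j (column) on
#' target channel i (row). `kind` states what the values are:
#' `"tpdc"` (nonnegative band-averaged TPDC), `"binary"` (0/1 significance),
#' `"threshold"` (percentile cutoffs) or `"frequency"` (subject counts).
#'
#' @param values Numeric N x N matrix.
#' @param kind One of `"tpdc"`, `"binary"`, `"threshold"`, `"frequency"`.
#' @param channels Channel names (length N).
#' @param subject_id Identifier for provenance.
#' @return An object of class `"matrix_record"`.
#' @export
matrix_record <- function(values, kind = c("tpdc", "binary", "threshold", "frequency"),
                          channels = colnames(values), subject_id = "subject") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  if (is.null(channels)) stop("channel names are required", call. = FALSE)
  if (length(channels) != nrow(values))
    stop("channel count does not match matrix dimension", call. = FALSE)
  if (any(!is.finite(values))) stop("matrix contains non-finite values", call. = FALSE)
  if (kind == "binary" && !all(values %in% c(0, 1)))
    stop("binary matrix record may contain only 0 and 1", call. = FALSE)
  if (kind %in% c("tpdc", "threshold") && any(values < 0))
    stop(sprintf("%s matrix record must be nonnegative", kind), call. = FALSE)
  if (kind == "frequency" && any(values != round(values)))
    stop("frequency matrix record must be integer-valued", call. = FALSE)
  dimnames(values) <- list(channels, channels)
  structure(list(subject_id = subject_id, values = values, kind = kind,
                 channels = as.character(channels)),
            class = "matrix_record")
}

#' @export
print.matrix_record <- function(x, ...) {
  cat(sprintf("<matrix_record:%s> subject '%s', %dx%d (entry (i,j) = influence j -> i)\n",
              x$kind, x$subject_id, nrow(x$values), ncol(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Write a connectivity matrix record to TSV
#'
#' The file carries a comment header stating the kind, subject and the
#' orientation convention, then a channel-labelled table. Binary matrices
#' round-trip exactly; floats round-trip to full double precision.
#'
#' @param rec A [matrix_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "matrix_record"))
  fmt <- if (rec$kind %in% c("binary", "frequency")) {
    function(v) sprintf("%d", as.integer(v))
  } else {
    format_float
  }
  header <- sprintf("# kind=%s subject=%s convention=entry (i,j) is influence j->i",
                    rec$kind, rec$subject_id)
  body <- vapply(seq_len(nrow(rec$values)), function(i) {
    paste(c(rec$channels[i], fmt(rec$values[i, ])), collapse = "\t")
  }, character(1))
  lines <- c(header, paste(c("", rec$channels), collapse = "\t"), body)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a connectivity matrix record written by [save_matrix()]
#'
#' @param path Path to the TSV file.
#' @param channels Optional expected channel names; mismatch is an error.
#' @return A [matrix_record()].
#' @export
load_matrix <- function(path, channels = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#"))
    stop(sprintf("not a matrix record file: %s", path), call. = FALSE)
  kind <- sub(".*kind=([a-z]+).*", "\\1", lines[1])
  subject <- sub(".*subject=([^ ]+) .*", "\\1", lines[1])
  cols <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  rlab <- vapply(rows, `[`, character(1), 1)
  if (!identical(rlab, cols))
    stop(sprintf("row/column label mismatch in %s", path), call. = FALSE)
  if (!is.null(channels) && !identical(cols, as.character(channels)))
    stop(sprintf("channel mismatch in %s: expected %s", path,
                 paste(channels, collapse = ",")), call. = FALSE)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cols))))
  if (length(cols) == 1) vals <- matrix(vals, 1, 1)
  matrix_record(vals, kind = kind, channels = cols, subject_id = subject)
}
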