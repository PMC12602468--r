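# Subject-level bootstrap thresholding and group-level permutation inference.

#' Block-shuffle surrogate of a time series
#'
#' Partitions the series into `floor(T / window_len)` consecutive
#' non-overlapping blocks (trailing remainder dropped) and permutes the block
#' order. By default each channel receives its own independent random
#' permutation, which destroys the cross-channel lag structure that directed
#' measures feed on while preserving each channel's local autocorrelation —
#' the null the bootstrap threshold is built from. Supplying `perm` applies
#' an explicit permutation instead: a single vector is applied jointly to all
#' channels, a list gives one permutation per channel.
#'
#' @param x A [time_series_set()].
#' @param window_len Block length in samples (>= 2; `T >= 2 * window_len`).
#' @param seed RNG seed (used when `perm` is NULL).
#' @param perm Optional explicit block permutation(s).
#' @return A [time_series_set()] of length `floor(T / window_len) *
#'   window_len`.
#' @export
surrogate_series <- function(x, window_len = 10, seed = 1, perm = NULL) {
  stopifnot(inherits(x, "ts_set"))
  T_len <- nrow(x$data)
  if (window_len < 2) stop("window_len must be at least 2", call. = FALSE)
  if (T_len < 2 * window_len)
    stop(sprintf("window too long: T = %d < 2 * window_len = %d",
                 T_len, 2 * window_len), call. = FALSE)
  nb <- floor(T_len / window_len)
  keep <- seq_len(nb * window_len)
  blocks <- matrix(keep, nrow = window_len)   # column b = rows of block b
  N <- ncol(x$data)
  if (is.null(perm)) {
    perms <- with_seed(seed, replicate(N, sample.int(nb), simplify = FALSE))
  } else if (is.list(perm)) {
    stopifnot(length(perm) == N)
    perms <- lapply(perm, function(p) { stopifnot(length(p) == nb); as.integer(p) })
  } else {
    stopifnot(length(perm) == nb)
    perms <- rep(list(as.integer(perm)), N)
  }
  out <- matrix(0, nb * window_len, N)
  for (j in seq_len(N))
    out[, j] <- x$data[as.vector(blocks[, perms[[j]]]), j]
  time_series_set(out, TR = x$TR, channels = x$channels,
                  subject_id = paste0(x$subject_id, "_surrogate"), group = x$group)
}

#' Subject-level bootstrap threshold for a TPDC matrix
#'
#' Recomputes the full TPDC matrix on `n_shuffles` block-shuffle surrogates
#' of the series and takes, per connection, the given percentile of the
#' surrogate distribution as that connection's significance threshold
#' (defaults: 100 shuffles, 99th percentile).
#'
#' @param x A [time_series_set()].
#' @param p Model order.
#' @param band Frequency band in Hz.
#' @param cfg An [ekf_config()].
#' @param n_shuffles Number of surrogates (>= 10).
#' @param percentile Threshold percentile in (0, 100).
#' @param window_len Surrogate block length in samples.
#' @param seed RNG seed.
#' @return An object of class `"bootstrap_null"`: `threshold` (a
#'   [matrix_record()] of kind `"threshold"`), `surrogates` (N x N x
#'   n_shuffles array of surrogate TPDC values), plus the settings.
#' @export
bootstrap_threshold <- function(x, p = 1, band = c(0.009, 0.08),
                                cfg = ekf_config(), n_shuffles = 100,
                                percentile = 99, window_len = 10, seed = 1) {
  stopifnot(inherits(x, "ts_set"))
  if (n_shuffles < 10) stop("n_shuffles must be at least 10", call. = FALSE)
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)", call. = FALSE)
  N <- ncol(x$data)
  sur <- array(0, dim = c(N, N, n_shuffles))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_shuffles))
  for (s in seq_len(n_shuffles)) {
    xs <- surrogate_series(x, window_len = window_len, seed = seeds[s])
    sur[, , s] <- tpdc_values_fast(xs$data, x$TR, p = p, band = band, cfg = cfg)
  }
  thr <- apply(sur, c(1, 2), percentile_cut, percentile = percentile)
  structure(list(threshold = matrix_record(thr, kind = "threshold",
                                           channels = x$channels,
                                           subject_id = x$subject_id),
                 surrogates = sur, n_shuffles = n_shuffles,
                 percentile = percentile, window_len = window_len, seed = seed),
            class = "bootstrap_null")
}

#' Binarize a TPDC matrix against its bootstrap threshold
#'
#' A connection is significant (1) iff the observed TPDC strictly exceeds
#' its per-connection threshold; the diagonal is forced to 0 (self-influence
#' is not a connection of interest).
#'
#' @param tpdc_rec A [matrix_record()] of kind `"tpdc"`.
#' @param null A [bootstrap_threshold()] result (or a `"threshold"` matrix
#'   record).
#' @return A [matrix_record()] of kind `"binary"`.
#' @export
binarize <- function(tpdc_rec, null) {
  stopifnot(inherits(tpdc_rec, "matrix_record"), tpdc_rec$kind == "tpdc")
  thr <- if (inherits(null, "bootstrap_null")) null$threshold else null
  stopifnot(inherits(thr, "matrix_record"), thr$kind == "threshold")
  if (!identical(dim(tpdc_rec$values), dim(thr$values)) ||
      !identical(tpdc_rec$channels, thr$channels))
    stop("shape/channel mismatch between TPDC and threshold", call. = FALSE)
  b <- (tpdc_rec$values > thr$values) * 1
  diag(b) <- 0
  matrix_record(b, kind = "binary", channels = tpdc_rec$channels,
                subject_id = tpdc_rec$subject_id)
}

# Degree-preserving rewiring of one binary off-diagonal adjacency via edge
# swaps: (a->b, c->d) => (a->d, c->b), preserving all row and column sums.
degree_preserving_shuffle <- function(b) {
  edges <- which(b == 1, arr.ind = TRUE)
  m <- nrow(edges)
  if (m < 2) return(b)
  for (it in seq_len(10 * m)) {
    pick <- sample.int(m, 2)
    e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
    t1 <- e1[1]; s1 <- e1[2]; t2 <- e2[1]; s2 <- e2[2]
    if (t1 == s2 || t2 == s1) next                 # would create self-loops
    if (b[t1, s2] == 1 || b[t2, s1] == 1) next     # would collide
    b[t1, s1] <- 0; b[t2, s2] <- 0
    b[t1, s2] <- 1; b[t2, s1] <- 1
    edges[pick[1], ] <- c(t1, s2); edges[pick[2], ] <- c(t2, s1)
  }
  b
}

#' Group-level permutation inference on binary adjacency stacks
#'
#' The observed frequency matrix is the cellwise sum of the subjects' binary
#' matrices. Each of `n_perm` permutations independently shuffles every
#' subject's 42 off-diagonal cells (preserving that subject's total edge
#' count) and re-aggregates into a null frequency matrix; the per-connection
#' threshold is the given percentile of its null distribution, and a group
#' edge is significant iff its observed frequency strictly exceeds the
#' threshold. Defaults: 1000 permutations, 99th percentile.
#'
#' @param binaries List of `"binary"` [matrix_record()]s (>= 2 subjects,
#'   shared channels).
#' @param n_perm Number of permutations.
#' @param percentile Threshold percentile in (0, 100).
#' @param seed RNG seed.
#' @param method `"flat"` (uniform shuffle of off-diagonal cells, the
#'   default) or `"degree"` (degree-preserving edge swaps, preserving each
#'   subject's row and column sums).
#' @return An object of class `"group_null"`: `observed` (frequency
#'   [matrix_record()]), `threshold`, `significant` (binary
#'   [matrix_record()]), `null_frequencies` (n_perm x N x N array) and the
#'   settings.
#' @export
group_significance <- function(binaries, n_perm = 1000, percentile = 99,
                               seed = 1, method = c("flat", "degree")) {
  method <- match.arg(method)
  stopifnot(is.list(binaries), length(binaries) >= 2)
  channels <- binaries[[1]]$channels
  for (b in binaries) {
    if (!inherits(b, "matrix_record") || b$kind != "binary")
      stop("group_significance requires binary matrix records", call. = FALSE)
    if (!identical(b$channels, channels))
      stop("all subjects must share the same channels", call. = FALSE)
  }
  N <- length(channels)
  off <- which(diag(N) == 0)          # 42 off-diagonal linear indices
  stack <- vapply(binaries, function(b) b$values[off], numeric(length(off)))
  observed <- matrix(0, N, N)
  observed[off] <- rowSums(stack)
  nulls <- array(0, dim = c(n_perm, N, N))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      freq <- numeric(length(off))
      if (method == "flat") {
        for (s in seq_len(ncol(stack)))
          freq <- freq + stack[sample.int(length(off)), s]
      } else {
        for (s in seq_len(ncol(stack))) {
          b <- matrix(0, N, N); b[off] <- stack[, s]
          freq <- freq + degree_preserving_shuffle(b)[off]
        }
      }
      m <- matrix(0, N, N); m[off] <- freq
      nulls[r, , ] <- m
    }
  })
  thr <- apply(nulls, c(2, 3), percentile_cut, percentile = percentile)
  sig <- (observed > thr) * 1
  diag(sig) <- 0
  structure(list(observed = matrix_record(observed, kind = "frequency",
                                          channels = channels, subject_id = "group"),
                 threshold = matrix_record(thr, kind = "threshold",
                                           channels = channels, subject_id = "group"),
                 significant = matrix_record(sig, kind = "binary",
                                             channels = channels, subject_id = "group"),
                 null_frequencies = nulls, n_perm = n_perm,
                 percentile = percentile, n_subjects = length(binaries),
                 method = method, seed = seed),
            class = "group_null")
}

#' @export
print.group_null <- function(x, ...) {
  cat(sprintf("<group_null> %d subjects, %d permutations, %gth percentile (%s shuffle)\n",
              x$n_subjects, x$n_perm, x$percentile, x$method))
  cat(sprintf("significant directed edges: %d\n", sum(x$significant$values)))
  invisible(x)
}
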