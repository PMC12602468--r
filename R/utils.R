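# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic entry points funnel their `seed` argument through
# here so results are reproducible and side-effect free.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Fixed float formatting for deterministic writers: 17 significant digits is
# lossless for doubles.
format_float <- function(x) sprintf("%.17g", x)

# Spectral radius of a square matrix.
spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

# Strict percentile helper used by all thresholding code (type-7 quantile,
# documented in the methods vignette).
percentile_cut <- function(x, percentile) {
  unname(quantile(x, probs = percentile / 100, type = 7, names = FALSE))
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
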