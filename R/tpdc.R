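# Time-varying MVAR estimation (dual extended Kalman filter) and temporal
# partial directed coherence.
#
# Model: X(t) = sum_k A_k(t) X(t-k) + E(t), default order p = 1.
# Spectral transfer: Abar(f, t) = I - sum_k A_k(t) exp(-i 2 pi f k TR).
# TPDC: pi_ij(f, t) = |Abar_ij| / sqrt(sum_k |Abar_kj|^2), so the squared
# directed influences out of each source column sum to 1 at every (f, t).

#' Tuning constants for the dual extended Kalman filter
#'
#' The estimation strategy couples two filters run forward once per series: a
#' state filter (signal estimate given the current coefficients) feeding a
#' parameter filter whose state is the stacked coefficient matrix with
#' random-walk dynamics.
#'
#' @param process_noise Variance of the coefficient random walk per step.
#'   Controls the tracking/variance trade-off: larger follows changes faster
#'   but inflates coefficient noise (and with it a positive bias in |TPDC| on
#'   null couplings).
#' @param init_param_cov Initial diagonal covariance of the coefficient
#'   filter around its stationary (OLS) initializer.
#' @param state_noise Observation-noise variance assumed by the state filter.
#' @param n_freqs Size of the uniform frequency grid over (0, Nyquist].
#' @param burn_fraction Fraction of initial estimated time points excluded
#'   from time averaging (filter transient), in \[0, 0.5\].
#' @param cov_cap Divergence guard: error if a parameter-filter covariance
#'   trace exceeds this.
#' @return An object of class `"ekf_config"`.
#' @export
ekf_config <- function(process_noise = 1e-6, init_param_cov = 1e-3,
                       state_noise = 1e-2, n_freqs = 128,
                       burn_fraction = 0.1, cov_cap = 1e6) {
  assert_scalar_num(process_noise, "process_noise", positive = TRUE)
  assert_scalar_num(init_param_cov, "init_param_cov", positive = TRUE)
  assert_scalar_num(state_noise, "state_noise", positive = TRUE)
  if (n_freqs < 8) stop("n_freqs must be at least 8", call. = FALSE)
  if (burn_fraction < 0 || burn_fraction > 0.5)
    stop("burn_fraction must lie in [0, 0.5]", call. = FALSE)
  structure(list(process_noise = process_noise, init_param_cov = init_param_cov,
                 state_noise = state_noise, n_freqs = n_freqs,
                 burn_fraction = burn_fraction, cov_cap = cov_cap),
            class = "ekf_config")
}

#' Stationary multivariate AR fit by ordinary least squares
#'
#' Each channel is regressed on all channels' previous `p` values; used to
#' initialize the dual Kalman filter and as the stationary-limit reference.
#'
#' @param x A [time_series_set()].
#' @param p Model order (>= 1).
#' @return List with `A` (N x N*p coefficient matrix, lag blocks left to
#'   right), `Sigma` (N x N innovation covariance), `p`, `channels`.
#' @export
fit_stationary_var <- function(x, p = 1) {
  stopifnot(inherits(x, "ts_set"), p >= 1)
  T_len <- nrow(x$data); N <- ncol(x$data)
  if (T_len <= N * p + 10)
    stop(sprintf("too few time points (T = %d) for VAR(%d) with %d channels; need T > %d",
                 T_len, p, N, N * p + 10), call. = FALSE)
  fit <- .ols_var_cpp(x$data, as.integer(p))
  lags <- paste0("lag", rep(seq_len(p), each = N))
  dimnames(fit$A) <- list(x$channels, paste(lags, rep(x$channels, p), sep = "."))
  dimnames(fit$Sigma) <- list(x$channels, x$channels)
  list(A = fit$A, Sigma = fit$Sigma, p = p, channels = x$channels)
}

#' Estimate time-varying MVAR coefficients with a dual extended Kalman filter
#'
#' Two coupled filters are run forward once. The state filter estimates the
#' signal given the current coefficients; its filtered lagged states feed the
#' parameter filter, which treats the stacked coefficients as a random-walk
#' state (process noise `cfg$process_noise` on each coefficient) observed
#' through the VAR regression. Initialization comes from
#' [fit_stationary_var()]. Deterministic given its inputs.
#'
#' @param x A [time_series_set()].
#' @param p Model order (default 1, the pipeline default).
#' @param cfg An [ekf_config()].
#' @return An object of class `"tvar_model"`: `coeffs` is an N x (N*p) x
#'   (T-p) array of coefficient matrices (columns grouped by lag),
#'   `innovation_cov` the stationary residual covariance,
#'   `estimation_range` the covered time indices (p+1 .. T), plus `order`,
#'   `channels`, `TR`, `cfg`.
#' @export
dual_ekf_tvar <- function(x, p = 1, cfg = ekf_config()) {
  stopifnot(inherits(x, "ts_set"), inherits(cfg, "ekf_config"), p >= 1)
  T_len <- nrow(x$data); N <- ncol(x$data)
  if (T_len <= N * p + 10)
    stop(sprintf("too few time points (T = %d) for order %d", T_len, p), call. = FALSE)
  fit <- .dekf_cpp(x$data, as.integer(p), cfg$process_noise, cfg$init_param_cov,
                   cfg$state_noise, cfg$cov_cap)
  structure(list(order = p, coeffs = fit$coeffs,
                 innovation_cov = fit$Sigma, stationary_A = fit$A0,
                 estimation_range = (p + 1):T_len,
                 channels = x$channels, TR = x$TR, cfg = cfg),
            class = "tvar_model")
}

#' @export
print.tvar_model <- function(x, ...) {
  cat(sprintf("<tvar_model> order %d, %d channels, %d estimated time points, TR = %g s\n",
              x$order, length(x$channels), dim(x$coeffs)[3], x$TR))
  invisible(x)
}

# Uniform frequency grid over (0, Nyquist].
frequency_grid <- function(TR, n_freqs) {
  nyquist <- 1 / (2 * TR)
  seq_len(n_freqs) / n_freqs * nyquist
}

#' Spectral transfer matrices of a time-varying MVAR model
#'
#' Evaluates `Abar(f, t) = I - sum_k A_k(t) exp(-i 2 pi f k TR)` on a uniform
#' grid of `n_freqs` frequencies in (0, Nyquist], Nyquist = 1/(2 TR).
#'
#' @param model A [dual_ekf_tvar()] result (or compatible `tvar_model`).
#' @param n_freqs Number of grid frequencies (>= 8); defaults to the model's
#'   EKF configuration.
#' @return An object of class `"spectral_transfer"`: `values` is a complex
#'   N x N x n_freqs x Tt array, `freqs` the grid in Hz, plus `channels`,
#'   `TR`.
#' @export
spectral_transfer <- function(model, n_freqs = model$cfg$n_freqs) {
  stopifnot(inherits(model, "tvar_model"))
  if (n_freqs < 8) stop("n_freqs must be at least 8", call. = FALSE)
  freqs <- frequency_grid(model$TR, n_freqs)
  N <- length(model$channels)
  p <- model$order
  Tt <- dim(model$coeffs)[3]
  vals <- array(0+0i, dim = c(N, N, n_freqs, Tt))
  I_N <- diag(N)
  for (f in seq_along(freqs)) {
    ph <- exp(-2i * pi * freqs[f] * seq_len(p) * model$TR)
    for (t in seq_len(Tt)) {
      At <- model$coeffs[, , t]
      if (is.null(dim(At))) At <- matrix(At, N, N * p)
      Abar <- I_N + 0i
      for (k in seq_len(p))
        Abar <- Abar - At[, ((k - 1) * N + 1):(k * N), drop = FALSE] * ph[k]
      vals[, , f, t] <- Abar
    }
  }
  structure(list(values = vals, freqs = freqs, channels = model$channels,
                 TR = model$TR),
            class = "spectral_transfer")
}

#' Temporal partial directed coherence from spectral transfer matrices
#'
#' `pi_ij(f, t) = |Abar_ij(f, t)| / sqrt(sum_k |Abar_kj(f, t)|^2)`: the
#' column-normalized transfer magnitude, quantifying the directed influence
#' of source channel j on target i at frequency f and time t. The squared
#' entries of every source column sum to 1.
#'
#' @param transfer A [spectral_transfer()] object.
#' @return An object of class `"tpdc_tensor"`: `values` is a nonnegative
#'   N x N x n_freqs x Tt array with the same `freqs`, `channels`, `TR`.
#' @export
compute_tpdc <- function(transfer) {
  stopifnot(inherits(transfer, "spectral_transfer"))
  mag <- Mod(transfer$values)
  denom <- sqrt(apply(mag^2, c(2, 3, 4), sum))   # column norm per (j, f, t)
  zero <- which(denom <= 0, arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop(sprintf("degenerate transfer: zero column norm for source '%s' at %g Hz",
                 transfer$channels[zero[1, 1]], transfer$freqs[zero[1, 2]]),
         call. = FALSE)
  d <- dim(mag)
  pi_vals <- mag / aperm(array(denom, dim = c(d[2], d[3], d[4], d[1])), c(4, 1, 2, 3))
  structure(list(values = pi_vals, freqs = transfer$freqs,
                 channels = transfer$channels, TR = transfer$TR),
            class = "tpdc_tensor")
}

#' Band- and time-average a TPDC tensor into a connectivity matrix
#'
#' Arithmetic mean of `pi_ij(f, t)` over the grid frequencies falling inside
#' `band` and over time points after discarding the initial `burn_fraction`
#' of the estimation range.
#'
#' @param pi_tensor A [compute_tpdc()] result.
#' @param band Frequency band `c(f_lo, f_hi)` in Hz; default 0.009-0.08 Hz,
#'   the resting-state BOLD band.
#' @param burn_fraction Initial fraction of time points to drop.
#' @param subject_id Identifier stored in the returned record.
#' @return A [matrix_record()] of kind `"tpdc"` with attribute `"band"`.
#' @export
band_average <- function(pi_tensor, band = c(0.009, 0.08), burn_fraction = 0.1,
                         subject_id = "subject") {
  stopifnot(inherits(pi_tensor, "tpdc_tensor"), length(band) == 2, band[1] < band[2])
  nyquist <- 1 / (2 * pi_tensor$TR)
  if (band[1] <= 0 || band[2] > nyquist + 1e-12)
    stop(sprintf("band must lie within (0, %g] Hz", nyquist), call. = FALSE)
  sel <- which(pi_tensor$freqs >= band[1] & pi_tensor$freqs <= band[2])
  if (length(sel) == 0)
    stop("no grid frequencies inside the requested band", call. = FALSE)
  Tt <- dim(pi_tensor$values)[4]
  burn <- floor(burn_fraction * Tt)
  keep_t <- (burn + 1):Tt
  vals <- apply(pi_tensor$values[, , sel, keep_t, drop = FALSE], c(1, 2), mean)
  rec <- matrix_record(vals, kind = "tpdc", channels = pi_tensor$channels,
                       subject_id = subject_id)
  attr(rec, "band") <- band
  rec
}

#' Full subject-level TPDC pipeline
#'
#' Convenience front end chaining [dual_ekf_tvar()], the spectral transfer,
#' TPDC normalization and band averaging. Uses a compiled path that evaluates
#' the transfer only at the grid frequencies inside `band` (identical to
#' computing the full grid and then band-averaging), which keeps the
#' bootstrap affordable.
#'
#' @param x A [time_series_set()].
#' @param p Model order.
#' @param band Frequency band in Hz.
#' @param cfg An [ekf_config()].
#' @return A [matrix_record()] of kind `"tpdc"`.
#' @export
tpdc <- function(x, p = 1, band = c(0.009, 0.08), cfg = ekf_config()) {
  stopifnot(inherits(x, "ts_set"))
  model <- dual_ekf_tvar(x, p = p, cfg = cfg)
  tpdc_from_model(model, band = band, subject_id = x$subject_id)
}

# Band-averaged TPDC from an already-fitted tvar_model (compiled fast path).
tpdc_from_model <- function(model, band = c(0.009, 0.08), subject_id = "subject") {
  freqs <- frequency_grid(model$TR, model$cfg$n_freqs)
  sel <- freqs[freqs >= band[1] & freqs <= band[2]]
  if (length(sel) == 0) stop("no grid frequencies inside the requested band",
                             call. = FALSE)
  Tt <- dim(model$coeffs)[3]
  burn <- floor(model$cfg$burn_fraction * Tt)
  vals <- .tpdc_band_cpp(model$coeffs, sel, model$TR, as.integer(burn))
  rec <- matrix_record(vals, kind = "tpdc", channels = model$channels,
                       subject_id = subject_id)
  attr(rec, "band") <- band
  rec
}

# Matrix-in, matrix-out fast path used inside the bootstrap loop: identical
# computation to tpdc() without the container construction.
tpdc_values_fast <- function(data, TR, p = 1, band = c(0.009, 0.08),
                             cfg = ekf_config()) {
  fit <- .dekf_cpp(data, as.integer(p), cfg$process_noise, cfg$init_param_cov,
                   cfg$state_noise, cfg$cov_cap)
  freqs <- frequency_grid(TR, cfg$n_freqs)
  sel <- freqs[freqs >= band[1] & freqs <= band[2]]
  Tt <- dim(fit$coeffs)[3]
  .tpdc_band_cpp(fit$coeffs, sel, TR, as.integer(floor(cfg$burn_fraction * Tt)))
}

# Closed-form band-averaged PDC of a fixed (stationary) coefficient matrix:
# the static reference used by the stationary-limit checks.
static_pdc <- function(A, TR, band = c(0.009, 0.08), n_freqs = 128, p = 1) {
  N <- nrow(A)
  freqs <- frequency_grid(TR, n_freqs)
  sel <- freqs[freqs >= band[1] & freqs <= band[2]]
  acc <- matrix(0, N, N)
  for (f in sel) {
    Abar <- diag(N) + 0i
    for (k in seq_len(p))
      Abar <- Abar - A[, ((k - 1) * N + 1):(k * N), drop = FALSE] *
        exp(-2i * pi * f * k * TR)
    mag <- Mod(Abar)
    cn <- sqrt(colSums(mag^2))
    acc <- acc + sweep(mag, 2, cn, "/")
  }
  out <- acc / length(sel)
  dimnames(out) <- list(rownames(A)[seq_len(N)], rownames(A)[seq_len(N)])
  out
}
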