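# Shared fixtures built in code.

# Two-channel template with a single directed coupling C1 -> C2.
two_channel_template <- function(coupling = 0.4, self = 0.5) {
  tpl <- make_template("custom", 0, self, edges = list(), channels = c("C1", "C2"))
  tpl$coupling[2, 1] <- coupling
  if (coupling != 0) tpl$edge_list <- list(c("C1", "C2"))
  tpl
}

# Fixed white-noise (diagonal-free) template over the Yeo-7 channels.
white_template <- function() {
  make_template("custom", 0, 0, edges = list())
}

# Construct a tvar_model by hand from a coefficient array (N x N*p x Tt),
# bypassing estimation; used to feed the spectral stage directly.
manual_tvar_model <- function(coeffs, TR = 2.0, channels = NULL,
                              cfg = ekf_config()) {
  N <- dim(coeffs)[1]
  p <- dim(coeffs)[2] / N
  if (is.null(channels)) channels <- paste0("ch", seq_len(N))
  structure(list(order = p, coeffs = coeffs,
                 innovation_cov = diag(N),
                 estimation_range = (p + 1):(p + dim(coeffs)[3]),
                 channels = channels, TR = TR, cfg = cfg),
            class = "tvar_model")
}

# Feature tables built directly from per-subject matrices: two groups of
# Gaussian TPDC-like matrices whose means differ on `shift_cells` (matrix of
# (row, col) indices) by `shift`.
gaussian_feature_cohort <- function(n_per_class = 50, shift_cells = rbind(c(2, 6)),
                                    shift = 0.3, sd = 0.05, seed = 1) {
  ch <- yeo7_channels()
  base <- matrix(0.1, 7, 7)
  diag(base) <- 0.9
  set.seed(seed)
  mats <- list()
  labels <- character(0)
  for (g in 1:2) {
    mu <- base
    if (g == 2) for (r in seq_len(nrow(shift_cells)))
      mu[shift_cells[r, 1], shift_cells[r, 2]] <- mu[shift_cells[r, 1], shift_cells[r, 2]] + shift
    for (s in seq_len(n_per_class)) {
      v <- abs(mu + matrix(rnorm(49, sd = sd), 7, 7))
      mats[[length(mats) + 1]] <- matrix_record(v, kind = "tpdc", channels = ch,
                                                subject_id = sprintf("g%d_%02d", g, s))
      labels <- c(labels, paste0("group", g))
    }
  }
  build_features(mats, labels)
}
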