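# Spectral transfer, TPDC normalization, band averaging.

# Independent brute-force evaluation of the transfer definition, written as
# plain loops so it shares nothing with the package implementation.
brute_transfer <- function(coeffs, freqs, TR) {
  N <- dim(coeffs)[1]; p <- dim(coeffs)[2] / N; Tt <- dim(coeffs)[3]
  out <- array(0+0i, dim = c(N, N, length(freqs), Tt))
  for (f in seq_along(freqs)) for (t in seq_len(Tt)) for (i in 1:N) for (j in 1:N) {
    v <- if (i == j) 1 + 0i else 0 + 0i
    for (k in 1:p)
      v <- v - coeffs[i, (k - 1) * N + j, t] * exp(-2i * pi * freqs[f] * k * TR)
    out[i, j, f, t] <- v
  }
  out
}

test_that("spectral transfer equals the brute-force evaluation of its definition", {
  set.seed(4)
  coeffs <- array(rnorm(3 * 6 * 5, sd = 0.2), dim = c(3, 6, 5))  # N=3, p=2, Tt=5
  model <- manual_tvar_model(coeffs, TR = 2.0)
  st <- spectral_transfer(model, n_freqs = 8)
  expect_equal(st$values, brute_transfer(coeffs, st$freqs, 2.0), tolerance = 1e-12)
})

test_that("zero coefficients give the identity transfer and identity TPDC pattern", {
  coeffs <- array(0, dim = c(4, 4, 3))
  st <- spectral_transfer(manual_tvar_model(coeffs), n_freqs = 8)
  for (f in 1:8) expect_equal(st$values[, , f, 1], diag(4) + 0i)
  pi_t <- compute_tpdc(st)
  for (f in 1:8) {
    expect_equal(diag(pi_t$values[, , f, 2]), rep(1, 4))
    off <- pi_t$values[, , f, 2]; diag(off) <- 0
    expect_true(all(off == 0))
  }
})

test_that("diagonal transfer follows the closed form 1 - a e^{-i w}", {
  coeffs <- array(diag(0.5, 3), dim = c(3, 3, 2))
  st <- spectral_transfer(manual_tvar_model(coeffs, TR = 2.0), n_freqs = 16)
  for (f in c(1, 16)) {
    expected <- 1 - 0.5 * exp(-2i * pi * st$freqs[f] * 2.0)
    expect_equal(diag(st$values[, , f, 1]), rep(expected, 3), tolerance = 1e-12)
    off <- st$values[, , f, 1]; diag(off) <- 0
    expect_true(all(off == 0))
  }
})

test_that("TPDC columns are normalized: sum_i pi_ij^2 = 1 at every (j, f, t)", {
  set.seed(77)
  for (rep in 1:5) {
    coeffs <- array(rnorm(5 * 5 * 4, sd = 0.25), dim = c(5, 5, 4))
    pi_t <- compute_tpdc(spectral_transfer(manual_tvar_model(coeffs), n_freqs = 8))
    sums <- apply(pi_t$values^2, c(2, 3, 4), sum)
    expect_true(all(abs(sums - 1) < 1e-10))
  }
})

test_that("a one-directional system yields strictly one-sided TPDC", {
  # channel 1 drives channel 2; the reverse direction must be exactly zero
  A <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)  # A[2,1] = 0.4, A[1,2] = 0
  coeffs <- array(A, dim = c(2, 2, 3))
  pi_t <- compute_tpdc(spectral_transfer(manual_tvar_model(coeffs, TR = 2.0), n_freqs = 16))
  expect_true(all(pi_t$values[1, 2, , ] == 0))  # no 2 -> 1 influence
  expect_true(all(pi_t$values[2, 1, , ] > 0))   # 1 -> 2 influence at all f
  # closed form at each frequency: |0.4 e^{-iw}| / sqrt(|1-0.5e^{-iw}|^2 + 0.16)
  w <- 2 * pi * pi_t$freqs * 2.0
  expected <- 0.4 / sqrt(Mod(1 - 0.5 * exp(-1i * w))^2 + 0.16)
  expect_equal(pi_t$values[2, 1, , 1], expected, tolerance = 1e-12)
})

test_that("degenerate zero transfer columns are reported with column and frequency", {
  st <- spectral_transfer(manual_tvar_model(array(0, dim = c(3, 3, 2))), n_freqs = 8)
  st$values[, 2, 3, ] <- 0 + 0i
  expect_error(compute_tpdc(st), "source 'ch2'")
})

test_that("band averaging is an arithmetic mean over in-band bins and kept time", {
  # constant pi in f and t -> band average equals that constant
  coeffs <- array(diag(0.5, 2), dim = c(2, 2, 10))
  pi_t <- compute_tpdc(spectral_transfer(manual_tvar_model(coeffs, TR = 2.0), n_freqs = 64))
  rec <- band_average(pi_t, band = c(0.009, 0.08), burn_fraction = 0.1)
  expect_equal(diag(rec$values), c(1, 1), ignore_attr = TRUE)  # diagonal-only: pi_jj = 1

  # hand-built tensor: band covering exactly two bins valued 0.2 and 0.4
  fake <- structure(list(values = array(0, dim = c(2, 2, 4, 3)),
                         freqs = c(0.01, 0.02, 0.03, 0.04),
                         channels = c("a", "b"), TR = 2.0),
                    class = "tpdc_tensor")
  fake$values[1, 2, , ] <- rep(c(0.2, 0.4, 0.9, 0.9), times = 3)
  rec <- band_average(fake, band = c(0.005, 0.025), burn_fraction = 0)
  expect_equal(rec$values[1, 2], 0.3)

  expect_error(band_average(fake, band = c(0.041, 0.05)), "no grid frequencies")
  expect_error(band_average(fake, band = c(0.01, 0.5)), "band must lie within")
})

test_that("the compiled band-TPDC path agrees with the staged computation", {
  tpl <- make_template("prodromal_pd", 0.3, 0.5)
  x <- simulate_subject(tpl, T_len = 300, seed = 12)
  model <- dual_ekf_tvar(x)
  staged <- band_average(compute_tpdc(spectral_transfer(model, 128)),
                         band = c(0.009, 0.08), burn_fraction = 0.1)
  fast <- tpdc(x)
  expect_equal(fast$values, staged$values, tolerance = 1e-12)
  # determinism of the full path
  expect_identical(fast$values, tpdc(x)$values)
})

test_that("estimated TPDC increases with the true coupling strength", {
  means <- vapply(c(0, 0.2, 0.4), function(cc) {
    tpl <- two_channel_template(cc)
    mean(vapply(1:20, function(s)
      tpdc(simulate_subject(tpl, T_len = 400, seed = s))$values[2, 1],
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
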