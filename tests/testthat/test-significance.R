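# Surrogates, bootstrap thresholds, binarization, group permutation nulls.

test_that("explicit block permutations rearrange rows as constructed", {
  m <- matrix(rep(1:10, 2), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  x <- time_series_set(m + 0.0, TR = 2, channels = c("a", "b"))
  # T=10, window 5, swap the two blocks jointly: rows 6-10 then 1-5
  sw <- surrogate_series(x, window_len = 5, perm = c(2, 1))
  expect_equal(sw$data[, 1], c(6:10, 1:5))
  expect_equal(sw$data[, 2], c(6:10, 1:5))
  # identity permutation leaves the series unchanged
  id <- surrogate_series(x, window_len = 5, perm = c(1, 2))
  expect_equal(id$data, x$data, ignore_attr = TRUE)
  # per-channel permutations applied channel by channel
  pc <- surrogate_series(x, window_len = 5, perm = list(c(2, 1), c(1, 2)))
  expect_equal(pc$data[, 1], c(6:10, 1:5))
  expect_equal(pc$data[, 2], 1:10)
})

test_that("random surrogates preserve each channel's sample multiset", {
  x <- simulate_subject(two_channel_template(0.4), T_len = 95, seed = 3)
  for (s in 1:5) {
    sur <- surrogate_series(x, window_len = 10, seed = s)
    expect_equal(nrow(sur$data), 90)  # trailing remainder dropped
    for (j in 1:2)
      expect_equal(sort(sur$data[, j]), sort(x$data[1:90, j]))
  }
  expect_error(surrogate_series(x, window_len = 60), "window too long")
  expect_error(surrogate_series(x, window_len = 1), "at least 2")
})

test_that("bootstrap thresholds are the per-cell percentile of the surrogate TPDC", {
  x <- simulate_subject(two_channel_template(0.5), T_len = 300, seed = 21)
  bn <- bootstrap_threshold(x, n_shuffles = 20, percentile = 99, seed = 4)
  expect_equal(dim(bn$surrogates), c(2, 2, 20))
  manual <- apply(bn$surrogates, c(1, 2), quantile, probs = 0.99, type = 7)
  expect_equal(bn$threshold$values, manual, ignore_attr = TRUE)
  expect_true(all(bn$threshold$values >= 0))
  expect_error(bootstrap_threshold(x, n_shuffles = 5), "at least 10")
  # determinism given the seed
  bn2 <- bootstrap_threshold(x, n_shuffles = 20, percentile = 99, seed = 4)
  expect_identical(bn$threshold$values, bn2$threshold$values)
})

test_that("a coupled connection beats its bootstrap threshold; a null one does not", {
  hits_coupled <- logical(20); hits_null <- logical(20)
  for (s in 1:20) {
    x <- simulate_subject(two_channel_template(0.5), T_len = 400, seed = 100 + s)
    obs <- tpdc(x)
    bn <- bootstrap_threshold(x, n_shuffles = 100, seed = 200 + s)
    b <- binarize(obs, bn)
    hits_coupled[s] <- b$values[2, 1] == 1   # true edge C1 -> C2
    hits_null[s] <- b$values[1, 2] == 1      # absent reverse edge
  }
  expect_gte(mean(hits_coupled), 0.9)
  expect_lte(mean(hits_null), 0.1)
})

test_that("binarization uses a strict inequality and forces the diagonal to zero", {
  ch <- c("a", "b")
  obs <- matrix_record(matrix(c(0.9, 0.3, 0.2, 0.9), 2, 2), "tpdc", ch)
  thr <- matrix_record(matrix(c(0.1, 0.2, 0.2, 0.1), 2, 2), "threshold", ch)
  b <- binarize(obs, thr)
  expect_equal(b$values[2, 1], 1)  # 0.3 > 0.2
  expect_equal(b$values[1, 2], 0)  # 0.2 == 0.2: ties are not significant
  expect_equal(diag(b$values), c(0, 0), ignore_attr = TRUE)
  # all-zero observed stays all zero
  z <- matrix_record(matrix(0, 2, 2), "tpdc", ch)
  expect_true(all(binarize(z, thr)$values == 0))
  bad <- matrix_record(matrix(0.1, 3, 3), "threshold", c("a", "b", "c"))
  expect_error(binarize(obs, bad), "mismatch")
})

test_that("a unanimous edge across 20 subjects is detected as group-significant", {
  ch <- yeo7_channels()
  one <- matrix(0, 7, 7, dimnames = list(ch, ch))
  one["SMN", "FPN"] <- 1
  bins <- lapply(1:20, function(i) matrix_record(one, "binary", ch,
                                                 subject_id = sprintf("s%02d", i)))
  gn <- group_significance(bins, n_perm = 1000, seed = 5)
  expect_equal(gn$observed$values["SMN", "FPN"], 20)
  expect_equal(gn$significant$values["SMN", "FPN"], 1)
  expect_equal(sum(gn$significant$values), 1)
  # permutations preserve each subject's edge count: every null frequency
  # matrix redistributes exactly 20 edges
  expect_true(all(apply(gn$null_frequencies, 1, sum) == 20))
})

test_that("all-zero binaries produce no significant group edges", {
  ch <- yeo7_channels()
  bins <- lapply(1:5, function(i)
    matrix_record(matrix(0, 7, 7), "binary", ch))
  gn <- group_significance(bins, n_perm = 200, seed = 1)
  expect_equal(sum(gn$significant$values), 0)
})

test_that("group permutation null is calibrated on exchangeable random binaries", {
  ch <- yeo7_channels()
  off <- which(diag(7) == 0)
  rates <- vapply(1:50, function(rep) {
    set.seed(rep)
    bins <- lapply(1:15, function(i) {
      m <- matrix(0, 7, 7)
      m[off] <- rbinom(42, 1, 0.5)
      matrix_record(m, "binary", ch)
    })
    gn <- group_significance(bins, n_perm = 300, seed = 1000 + rep)
    sum(gn$significant$values) / 42
  }, numeric(1))
  expect_lte(mean(rates), 0.02)
})

test_that("degree-preserving shuffles keep all row and column sums", {
  set.seed(31)
  b <- matrix(0, 7, 7)
  off <- which(diag(7) == 0)
  b[sample(off, 12)] <- 1
  for (i in 1:5) {
    s <- tpdcflow:::degree_preserving_shuffle(b)
    expect_equal(rowSums(s), rowSums(b))
    expect_equal(colSums(s), colSums(b))
    expect_true(all(diag(s) == 0))
  }
  # and the engine accepts the method switch end to end
  ch <- yeo7_channels()
  bins <- lapply(1:6, function(i) {
    m <- matrix(0, 7, 7); m[off[seq(i, i + 5)]] <- 1
    matrix_record(m, "binary", ch)
  })
  gn <- group_significance(bins, n_perm = 100, seed = 2, method = "degree")
  expect_true(all(apply(gn$null_frequencies, 1, sum) == sum(vapply(bins, function(b) sum(b$values), 1))))
})

test_that("group significance rejects non-binary input", {
  ch <- yeo7_channels()
  tp <- matrix_record(matrix(0.5, 7, 7), "tpdc", ch)
  expect_error(group_significance(list(tp, tp)), "binary")
})
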