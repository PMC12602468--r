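# Synthetic cohort generator: templates, VAR simulation, clinical scores.

test_that("built-in group templates carry the documented, distinct edge patterns", {
  tpls <- lapply(c("young_hc", "old_hc", "prodromal_pd", "manifest_pd"),
                 make_template, base_coupling = 0.3, self_coupling = 0.5)
  names(tpls) <- c("young_hc", "old_hc", "prodromal_pd", "manifest_pd")

  edge_key <- function(tpl) sort(vapply(tpl$edge_list, paste, character(1), collapse = ">"))
  keys <- lapply(tpls, edge_key)
  expect_length(unique(keys), 4)  # pairwise distinguishable

  # young controls keep bidirectional control<->somatomotor coupling
  expect_true(all(c("FPN>SMN", "SMN>FPN") %in% keys$young_hc))
  # the prodromal stage has no outgoing somatomotor edges
  sources <- vapply(tpls$prodromal_pd$edge_list, `[`, character(1), 1)
  expect_false("SMN" %in% sources)
  # the manifest stage adds somatomotor output to visual
  expect_true("SMN>VIS" %in% keys$manifest_pd)

  for (tpl in tpls) {
    expect_true(all(diag(tpl$coupling) == 0.5))
    expect_lt(max(Mod(eigen(tpl$coupling, only.values = TRUE)$values)), 1)
    # off-diagonal nonzeros exactly at the edge list
    off <- tpl$coupling; diag(off) <- 0
    expect_equal(sum(off != 0), length(tpl$edge_list))
  }
})

test_that("custom empty template is diagonal-only with spectral radius = self-coupling", {
  tpl <- make_template("custom", 0.0, 0.5, edges = list())
  expect_equal(tpl$coupling, diag(0.5, 7), ignore_attr = TRUE)
  expect_equal(max(Mod(eigen(tpl$coupling)$values)), 0.5)
})

test_that("template construction rejects unknown labels and unstable configurations", {
  expect_error(make_template("middle_aged"), "unknown group label")
  expect_error(make_template("custom", 0.0, 1.1, edges = list()), "unstable")
  expect_error(make_template("custom", 0.3, 0.5,
                             edges = list(c("FPN", "XXX"))), "unknown channel")
})

test_that("simulate_subject is deterministic and respects the AR(1) structure", {
  tpl <- make_template("custom", 0, 0.5, edges = list())
  a <- simulate_subject(tpl, T_len = 400, seed = 42)
  b <- simulate_subject(tpl, T_len = 400, seed = 42)
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(400L, 7L))

  # lag-1 autocorrelation of each independent AR(1) channel ~ self-coupling
  ac <- apply(a$data, 2, function(v) cor(v[-1], v[-length(v)]))
  expect_true(all(abs(ac - 0.5) < 0.1))

  expect_error(simulate_subject(tpl, T_len = 30), "at least 50")
  expect_error(simulate_subject(tpl, innovation_sd = 0), "positive")
})

test_that("a directed edge raises the lagged cross-correlation relative to no edge", {
  with_edge <- two_channel_template(0.4)
  no_edge <- two_channel_template(0.0)
  lag_xcor <- function(x) cor(x$data[-nrow(x$data), 1], x$data[-1, 2])
  xc <- vapply(1:50, function(s) {
    c(lag_xcor(simulate_subject(with_edge, T_len = 200, seed = s)),
      lag_xcor(simulate_subject(no_edge, T_len = 200, seed = s)))
  }, numeric(2))
  expect_gt(mean(xc[1, ]), mean(xc[2, ]))
  expect_gt(mean(xc[1, ]) - mean(xc[2, ]), 0.1)
})

test_that("simulate_cohort keeps the bookkeeping and stores exact truth", {
  spec <- cohort_spec(list(list(template = make_template("young_hc"), n = 3),
                           list(template = make_template("manifest_pd"), n = 3)),
                      T_len = 80, seed = 7)
  coh <- simulate_cohort(spec)
  expect_length(coh$subjects, 6)
  expect_equal(vapply(coh$subjects, function(s) s$group, character(1)),
               rep(c("young_hc", "manifest_pd"), each = 3))
  # truth recorded per subject, stable, and jittered independently
  radii <- vapply(coh$truth, function(t) max(Mod(eigen(t$coupling)$values)), numeric(1))
  expect_true(all(radii < 1))
  expect_false(identical(coh$truth[[1]]$coupling, coh$truth[[2]]$coupling))
  # reproducibility: same spec -> identical cohort
  coh2 <- simulate_cohort(spec)
  expect_identical(coh$subjects[[5]]$data, coh2$subjects[[5]]$data)
  expect_identical(coh$clinical_scores, coh2$clinical_scores)
})

test_that("noiseless clinical model reproduces the true coupling exactly", {
  tpl <- make_template("young_hc")
  spec <- cohort_spec(list(list(template = tpl, n = 20)), T_len = 60,
                      clinical_model = list(list(edge = c("FPN", "SMN"),
                                                 score = "np3_total",
                                                 slope = 1, noise_sd = 0)),
                      seed = 3)
  coh <- simulate_cohort(spec)
  truth <- vapply(coh$truth, function(t) t$coupling["SMN", "FPN"], numeric(1))
  expect_equal(coh$clinical_scores$np3_total, truth)
  expect_equal(cor(truth, coh$clinical_scores$np3_total), 1.0)
})

test_that("clinical noise equal to the coupling SD attenuates Pearson r to ~ 1/sqrt(2)", {
  tpl <- make_template("young_hc")
  spec <- cohort_spec(list(list(template = tpl, n = 500)), T_len = 60,
                      coupling_jitter_sd = 0.05,
                      clinical_model = list(list(edge = c("FPN", "SMN"),
                                                 score = "np3_total",
                                                 slope = 1, noise_sd = 0.05)),
                      seed = 11)
  coh <- simulate_cohort(spec)
  truth <- vapply(coh$truth, function(t) t$coupling["SMN", "FPN"], numeric(1))
  r <- cor(truth, coh$clinical_scores$np3_total)
  expect_lt(abs(r - 1 / sqrt(2)), 0.08)
})

test_that("generated series are mean-stationary with spectral mass in the BOLD band", {
  tpl <- make_template("manifest_pd", 0.3, 0.5)
  # ensemble average of |mean(second half) - mean(first half)| stays within
  # 3 standard errors of zero
  gap <- vapply(1:20, function(s) {
    x <- simulate_subject(tpl, T_len = 400, seed = s)$data
    h <- nrow(x) / 2
    mean(colMeans(x[(h + 1):nrow(x), ]) - colMeans(x[1:h, ]))
  }, numeric(1))
  expect_lt(abs(mean(gap)), 3 * sd(gap) / sqrt(length(gap)))

  x <- simulate_subject(tpl, T_len = 400, seed = 1)
  sp <- apply(x$data, 2, function(v) {
    s <- stats::spec.pgram(stats::ts(v, deltat = 2), plot = FALSE, taper = 0)
    sum(s$spec[s$freq >= 0.009 & s$freq <= 0.08])
  })
  expect_true(all(sp > 0))
})
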