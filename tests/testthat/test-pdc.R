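# MVAR fitting and partial directed coherence.

test_that("fit_mvar recovers a known VAR(1) and rejects degenerate input", {
  set.seed(10)
  a1 <- rbind(c(0.5, 0.0), c(0.3, 0.4))
  x <- simulate_var(list(a1), 5000L)
  rownames(x) <- c("c1", "c2")
  fit <- fit_mvar_trial(x, order = 1L)
  expect_lt(max(abs(fit$coeffs[[1L]] - a1)), 0.05)

  # independent white noise: coefficients near zero
  set.seed(11)
  w <- matrix(rnorm(2 * 5000), 2, 5000)
  fitw <- fit_mvar_trial(w, order = 1L)
  # OLS standard error ~ 1/sqrt(n); 3 SEs
  expect_lt(max(abs(fitw$coeffs[[1L]])), 3 / sqrt(5000))

  expect_error(fit_mvar_trial(matrix(rnorm(10), 2, 5), order = 5L),
               class = "lpggnet_validation_error")
})

test_that("pdc matches the hand-evaluated closed form at f -> 0", {
  m <- structure(list(order = 1L,
                      coeffs = list(rbind(c(0.5, 0), c(0.3, 0.4))),
                      innovation_cov = diag(2), channel_names = c("a", "b")),
                 class = "lpggnet_mvar")
  # Abar(0) = I - A1 = [[0.5, 0], [-0.3, 0.6]]; column 1 norm = sqrt(0.34)
  v <- pdc(m, freqs = 1e-9, fs = 250)$values[, , 1L]
  expect_equal(v["b", "a"], 0.3 / sqrt(0.34), tolerance = 1e-6)
  expect_equal(v["a", "a"], 0.5 / sqrt(0.34), tolerance = 1e-6)
  expect_equal(v["a", "b"], 0, tolerance = 1e-9)
  expect_equal(v["b", "b"], 1, tolerance = 1e-9)
})

test_that("diagonal models give identity-patterned PDC", {
  m <- structure(list(order = 1L, coeffs = list(diag(c(0.5, -0.3, 0.2))),
                      innovation_cov = diag(3), channel_names = NULL),
                 class = "lpggnet_mvar")
  v <- pdc(m, freqs = c(5, 20, 40), fs = 250)$values
  for (k in 1:3) {
    expect_equal(v[, , k][lower.tri(v[, , k]) | upper.tri(v[, , k])],
                 rep(0, 6), tolerance = 1e-12)
    expect_equal(diag(v[, , k]), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("column normalization identity holds on random stable models", {
  set.seed(12)
  for (i in 1:100) {
    ord <- sample(1:2, 1L)
    m <- random_stable_var(sample(2:5, 1L), ord)
    freqs <- sort(runif(4, 1, 124))
    v <- pdc(m, freqs, fs = 250)$values
    for (k in seq_along(freqs))
      expect_equal(colSums(v[, , k]^2), rep(1, ncol(v)), tolerance = 1e-6)
    expect_true(all(v >= 0 & v <= 1 + 1e-12))
  }
})

test_that("pdc_adjacency applies the printed normalization", {
  # hand case: averaged A = [[0, .5], [.5, 0]] => Achk = [[2/3, 1/3], [1/3, 2/3]]
  achk <- sym_normalize(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(unname(achk$values),
               rbind(c(2 / 3, 1 / 3), c(1 / 3, 2 / 3)), tolerance = 1e-12)

  # all-zero coupling: white noise gives near-diagonal-dominant Achk, and
  # the A = 0 limit is exactly the identity
  expect_equal(unname(sym_normalize(matrix(0, 3, 3))$values), diag(3),
               tolerance = 1e-12)

  set.seed(13)
  ep <- epoched_eeg(array(rnorm(3 * 3 * 400), c(3, 3, 400)), 250,
                    c(0L, 1L, 2L), c("a", "b", "c"))
  adj <- pdc_adjacency(ep, order = 2L)
  expect_true(adj$normalized)
  expect_identical(adj$labels, c("a", "b", "c"))
  expect_true(all(is.finite(adj$values)))

  expect_error(pdc_adjacency(ep, band = c(30, 8)),
               class = "lpggnet_validation_error")
})

test_that("pdc_adjacency is invariant to trial order", {
  set.seed(14)
  ep <- epoched_eeg(array(rnorm(4 * 2 * 300), c(4, 2, 300)), 250,
                    c(0L, 1L, 0L, 1L), c("a", "b"))
  shuf <- select_trials(ep, c(3L, 1L, 4L, 2L))
  expect_equal(pdc_adjacency(ep, order = 2L)$values,
               pdc_adjacency(shuf, order = 2L)$values, tolerance = 1e-12)
})

test_that("band-averaged PDC recovers injected directionality", {
  # unidirectional VAR coupling c1 -> c2: PDC(2<-1) should beat PDC(1<-2)
  set.seed(15)
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    x <- simulate_var(list(rbind(c(0.3, 0), c(0.4, 0.3))), 800L)
    rownames(x) <- c("c1", "c2")
    fit <- fit_mvar_trial(x, order = 2L)
    v <- pdc_band_mean(pdc(fit, seq(8, 30), fs = 250), c(8, 30))
    hits <- hits + (v[2L, 1L] > v[1L, 2L])
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})
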