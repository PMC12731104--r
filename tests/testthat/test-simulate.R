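# Synthetic session generator: protocol, balance, reproducibility, SNR
# limit, and PDC ground-truth recovery.

test_that("the default protocol yields a 288-trial balanced session", {
  sim <- simulate_session(sim_config(seed = 50L))
  ep <- sim$epochs
  expect_identical(n_trials(ep), 288L)
  expect_identical(unname(c(table(ep$labels))), rep(72L, 4L))
  expect_identical(dim(ep)[2:3], c(22L, 1000L))
  expect_equal(ep$fs, 250)
  # class balance holds per run (48 trials each)
  for (r in 1:6) {
    run_labels <- ep$labels[((r - 1) * 48 + 1):(r * 48)]
    expect_identical(unname(c(table(run_labels))), rep(12L, 4))
  }
})

test_that("simulation is bit-reproducible from its seed", {
  cfg <- sim_config(fs = 128, duration_s = 1, trials_per_class = 2L,
                    runs = 2L, seed = 51L)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(a$epochs$labels, b$epochs$labels)
  c2 <- simulate_session(sim_config(fs = 128, duration_s = 1,
                                    trials_per_class = 2L, runs = 2L,
                                    seed = 52L))
  expect_false(identical(a$epochs$data, c2$epochs$data))
})

test_that("focal electrodes are desynchronized in proportion to distance", {
  sim <- simulate_session(sim_config(fs = 128, duration_s = 2,
                                     trials_per_class = 4L, runs = 2L,
                                     snr = 4, seed = 53L))
  g <- sim$ground_truth$rhythm_gains
  # focal electrodes carry the maximal attenuation (gain = 1 - depth)
  expect_equal(g["C3", "0"], 1 - 0.6, tolerance = 1e-12)
  expect_equal(g["C4", "1"], 1 - 0.6, tolerance = 1e-12)
  # far-away electrodes barely attenuated for that class
  expect_gt(g["POz", "2"], 0.9)
  # gains are monotone in distance to the focal set
  expect_lt(g["C3", "0"], g["Cz", "0"])
  expect_lt(g["Cz", "0"], g["C6", "0"])
})

test_that("mu-band power separates classes at high SNR, not at snr -> 0", {
  band_power <- function(ep, ch) {
    idx <- match(ch, ep$channel_names)
    vapply(seq_len(n_trials(ep)), function(tr) {
      x <- ep$data[tr, idx, ]
      sp <- Mod(stats::fft(x))^2
      f <- (seq_along(x) - 1) * ep$fs / length(x)
      mean(sp[f >= 8 & f <= 12])
    }, 1)
  }
  hi <- simulate_session(sim_config(fs = 128, duration_s = 2,
                                    trials_per_class = 25L, runs = 1L,
                                    snr = 4, seed = 54L))$epochs
  bp <- band_power(hi, "C3")
  p_hi <- stats::t.test(bp[hi$labels == 0L], bp[hi$labels == 1L])$p.value
  expect_lt(p_hi, 1e-4)      # left-hand trials attenuate C3, right-hand do not

  lo <- simulate_session(sim_config(fs = 128, duration_s = 2,
                                    trials_per_class = 50L, runs = 1L,
                                    snr = 1e-6, seed = 55L))$epochs
  bp_lo <- band_power(lo, "C3")
  p_lo <- stats::t.test(bp_lo[lo$labels == 0L], bp_lo[lo$labels == 1L])$p.value
  expect_gt(p_lo, 0.01)      # no separability left in the snr -> 0 limit
})

test_that("injected directed coupling is recovered by PDC", {
  cp <- list(list(source = "C3", target = "C4", lag = 1L, gain = 0.4))
  ok_dir <- 0L
  ok_rank <- 0L
  mono <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    mk <- function(gain) sim_config(fs = 128, duration_s = 2,
                                    trials_per_class = 2L, runs = 1L,
                                    coupling = list(list(source = "C3",
                                                         target = "C4",
                                                         lag = 1L,
                                                         gain = gain)),
                                    seed = 600L + s)
    ep <- simulate_session(mk(0.4))$epochs
    rep1 <- ground_truth_pdc_check(ep, cp, order = 4L)
    ok_dir <- ok_dir + (rep1$pdc > rep1$pdc_reverse)
    ok_rank <- ok_rank + (rep1$null_quantile > 0.9)
    rep2 <- ground_truth_pdc_check(simulate_session(mk(0.8))$epochs, cp,
                                   order = 4L)
    mono <- mono + (rep2$pdc >= rep1$pdc)
  }
  expect_gte(ok_dir, ceiling(0.9 * n_rep))
  expect_gte(ok_rank, ceiling(0.9 * n_rep))
  expect_gte(mono, ceiling(0.9 * n_rep))
  expect_error(ground_truth_pdc_check(simulate_session(
    sim_config(trials_per_class = 1L, runs = 1L, seed = 1L))$epochs, NULL),
    class = "lpggnet_validation_error")
})

test_that("simulation config validates focal and coupling channels", {
  expect_error(sim_config(class_map = list(`0` = "NOPE", `1` = "C4",
                                           `2` = "Fz", `3` = "Pz")),
               class = "lpggnet_validation_error")
  expect_error(sim_config(coupling = list(list(source = "C3",
                                               target = "ZZ", lag = 1L,
                                               gain = 0.3))),
               class = "lpggnet_validation_error")
  expect_error(sim_config(snr = 0), class = "lpggnet_validation_error")
})
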