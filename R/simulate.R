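# Seeded generator of 4-class motor-imagery-like EEG.
#
# The stated world: class-balanced runs of 4 s trials at 250 Hz on the
# 22-channel montage; per-channel 1/f background noise; an 8-12 Hz mu
# rhythm on every channel whose amplitude is attenuated (event-related
# desynchronization) at the class's focal electrodes, with the attenuation
# spread to neighbours by a Gaussian of montage distances; optional
# injected directed VAR coupling edges as PDC ground truth.

#' Simulation configuration
#'
#' @param montage an `lpggnet_montage` (default the built-in 22 channels).
#' @param fs sampling rate in Hz (default 250).
#' @param duration_s trial length in seconds (default 4).
#' @param trials_per_class trials per class per run (default 12: six runs
#'   of 48 trials emulate one 288-trial session).
#' @param runs number of runs (default 6).
#' @param snr linear amplitude ratio of the mu rhythm to the background
#'   noise (default 1).
#' @param erd_depth fractional rhythm attenuation at a focal electrode
#'   (default 0.6).
#' @param class_map named list class id ("0".."3") -> focal electrodes.
#'   Default: left hand -> C3 area, right hand -> C4 area, feet -> Fz area,
#'   tongue -> CPz/Pz area.
#' @param coupling optional list of directed VAR edges, each a list with
#'   `source`, `target` (channel names), `lag` (samples), `gain`.
#' @param noise_exponent spectral exponent of the 1/f^a background power
#'   (default 1).
#' @param seed integer seed; the whole session is reproducible from it.
#' @return An object of class `lpggnet_sim_config`.
#' @export
sim_config <- function(montage = montage_dataset_a(), fs = 250,
                       duration_s = 4, trials_per_class = 12L, runs = 6L,
                       snr = 1, erd_depth = 0.6,
                       class_map = NULL, coupling = NULL,
                       noise_exponent = 1, seed = 1L) {
  if (is.null(class_map))
    class_map <- list(`0` = c("C3", "C5", "CP3"),
                      `1` = c("C4", "C6", "CP4"),
                      `2` = c("Fz", "FCz"),
                      `3` = c("CPz", "Pz"))
  if (trials_per_class < 1L) stop_validation("trials_per_class must be >= 1")
  if (snr <= 0) stop_validation("snr must be > 0")
  if (erd_depth < 0 || erd_depth > 1)
    stop_validation("erd_depth must be in [0, 1]")
  missing <- setdiff(unique(unlist(class_map)), montage$channel_names)
  if (length(missing))
    stop_validation(sprintf("focal electrode(s) not in montage: %s",
                            paste(missing, collapse = ", ")))
  for (e in coupling %||% list()) {
    bad <- setdiff(c(e$source, e$target), montage$channel_names)
    if (length(bad))
      stop_validation(sprintf("coupling channel(s) not in montage: %s",
                              paste(bad, collapse = ", ")))
  }
  structure(list(montage = montage, fs = fs, duration_s = duration_s,
                 trials_per_class = as.integer(trials_per_class),
                 runs = as.integer(runs), snr = snr, erd_depth = erd_depth,
                 class_map = class_map, coupling = coupling,
                 noise_exponent = noise_exponent, seed = as.integer(seed)),
            class = "lpggnet_sim_config")
}

# one trace of 1/f^a-shaped noise via spectral shaping of white noise
one_over_f_noise <- function(n, fs, exponent) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1L):1)) * fs / n
  shape <- ifelse(abs(f) < fs / n, 1, (abs(f))^(-exponent / 2))
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# band-limited mu rhythm: white noise band-passed to 8-12 Hz, unit sd
mu_rhythm <- function(n, fs) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- abs(c(0:(n %/% 2), -((n - n %/% 2 - 1L):1)) * fs / n)
  sp[f < 8 | f > 12] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a motor-imagery session
#'
#' Generates a full class-balanced session from a seeded configuration.
#' Each run contains `trials_per_class` trials per class in shuffled order.
#' Per trial and channel the signal is background `1/f` noise plus an
#' snr-scaled mu rhythm whose amplitude at channel `ch` for class `c` is
#' `1 - erd_depth * g(ch, c)`, where `g` is a Gaussian (bandwidth = the
#' montage's median pairwise distance) of the distance to the nearest focal
#' electrode of class `c` — focal sites are maximally desynchronized.
#' Injected coupling edges add a lagged, scaled copy of the source channel
#' to the target.
#'
#' @param config an `lpggnet_sim_config`.
#' @return A list with `epochs` (`lpggnet_epochs`) and `ground_truth`
#'   (class map, coupling edges, per-channel rhythm gains, seed).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "lpggnet_sim_config"))
  set.seed(config$seed)
  mont <- config$montage
  chans <- mont$channel_names
  n_ch <- length(chans)
  n_s <- round(config$fs * config$duration_s)
  n_per_run <- config$trials_per_class * 4L
  n_tr <- n_per_run * config$runs
  dists <- channel_distances(mont)
  delta <- gmd_delta(mont)$delta

  # per-class spatial gain profile of the ERD attenuation
  gains <- sapply(names(config$class_map), function(cl) {
    focal <- config$class_map[[cl]]
    d_min <- apply(dists[, focal, drop = FALSE], 1L, min)
    1 - config$erd_depth * exp(-d_min^2 / delta^2)
  })                                            # n_ch x 4

  labels <- integer(n_tr)
  data <- array(0, c(n_tr, n_ch, n_s))
  for (r in seq_len(config$runs)) {
    run_labels <- sample(rep(0:3, config$trials_per_class))
    for (i in seq_len(n_per_run)) {
      tr <- (r - 1L) * n_per_run + i
      cl <- run_labels[i]
      labels[tr] <- cl
      xt <- matrix(0, n_ch, n_s)
      for (ch in seq_len(n_ch))
        xt[ch, ] <- one_over_f_noise(n_s, config$fs, config$noise_exponent) +
          config$snr * gains[ch, cl + 1L] * mu_rhythm(n_s, config$fs)
      for (e in config$coupling %||% list()) {
        si <- match(e$source, chans)
        ti <- match(e$target, chans)
        lag <- as.integer(e$lag)
        xt[ti, (lag + 1L):n_s] <- xt[ti, (lag + 1L):n_s] +
          e$gain * xt[si, 1L:(n_s - lag)]
      }
      data[tr, , ] <- xt
    }
  }
  epochs <- epoched_eeg(data, config$fs, labels, chans,
                        class_names = c("left_hand", "right_hand",
                                        "feet", "tongue"))
  list(epochs = epochs,
       ground_truth = list(class_map = config$class_map,
                           coupling = config$coupling,
                           rhythm_gains = gains, seed = config$seed))
}

#' Check PDC recovery of injected coupling
#'
#' Computes the band-averaged directed PDC matrix of the epochs and ranks
#' the injected edges against the distribution of all non-edge, off-diagonal
#' entries.
#'
#' @param epochs an `lpggnet_epochs` with injected coupling.
#' @param coupling the injected edge list (as in [sim_config()]).
#' @param order MVAR order.
#' @param band frequency band in Hz.
#' @return A data.frame with one row per edge: source, target, pdc value,
#'   pdc of the reverse direction, and the quantile of the edge value within
#'   the non-edge distribution.
#' @export
ground_truth_pdc_check <- function(epochs, coupling, order = 5L,
                                   band = c(8, 30)) {
  if (length(coupling %||% list()) == 0L)
    stop_validation("no coupling edges to check")
  freqs <- seq(band[1L], band[2L], by = 1)
  models <- fit_mvar(epochs, order)
  acc <- 0
  for (m in models)
    acc <- acc + pdc_band_mean(pdc(m, freqs, epochs$fs), band)
  a <- acc / length(models)
  diag(a) <- NA
  chans <- epochs$channel_names
  edge_idx <- vapply(coupling, function(e)
    c(match(e$target, chans), match(e$source, chans)), numeric(2))
  is_edge <- matrix(FALSE, nrow(a), ncol(a))
  for (k in seq_len(ncol(edge_idx)))
    is_edge[edge_idx[1L, k], edge_idx[2L, k]] <- TRUE
  null_vals <- a[!is_edge & !is.na(a)]
  do.call(rbind, lapply(coupling, function(e) {
    ti <- match(e$target, chans)
    si <- match(e$source, chans)
    data.frame(source = e$source, target = e$target,
               pdc = a[ti, si], pdc_reverse = a[si, ti],
               null_quantile = mean(null_vals <= a[ti, si]))
  }))
}
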