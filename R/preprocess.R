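# Band-pass filtering and normalization.
#
# The band-pass is the zero-phase 6th-order Butterworth band-pass applied
# per trial and per channel. It is realized in the frequency domain: each
# trace is reflection-padded, transformed, multiplied by the *squared*
# magnitude response of the analog 6th-order Butterworth band-pass
# prototype (squaring is exactly the magnitude effect of forward-backward
# filtering, and the phase is identically zero), and transformed back.
# The analog prototype response after the low-pass -> band-pass transform
# s -> (s^2 + w0^2) / (B s) is
#   |H(f)|^2 = 1 / (1 + X^(2n)),   X = (f^2 - f0^2) / (f * B),
# with f0 = sqrt(low * high) the geometric centre and B = high - low.

butterworth_bp_gain <- function(f, low_hz, high_hz, order) {
  f0sq <- low_hz * high_hz
  bw <- high_hz - low_hz
  x <- ifelse(f == 0, Inf, (f^2 - f0sq) / (f * bw))
  1 / sqrt(1 + x^(2 * order))
}

filter_trace_fft <- function(x, fs, low_hz, high_hz, order) {
  n <- length(x)
  # reflection padding suppresses wrap-around transients at the trial edges
  pad <- min(n - 1L, max(64L, ceiling(3 * fs / low_hz)))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp)
  freqs <- c(0:(m %/% 2), -((m - m %/% 2 - 1L):1)) * fs / m
  gain <- butterworth_bp_gain(abs(freqs), low_hz, high_hz, order)^2
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every (trial, channel) trace with a zero-phase band-pass whose
#' magnitude equals that of a forward-backward 6th-order Butterworth design
#' (default band 0.5-40 Hz). Shape is preserved. The operator is linear.
#'
#' @param epochs an `lpggnet_epochs`.
#' @param low_hz lower band edge in Hz (> 0).
#' @param high_hz upper band edge in Hz (< fs/2).
#' @param order filter order (default 6).
#' @return A filtered `lpggnet_epochs`.
#' @export
eeg_bandpass <- function(epochs, low_hz = 0.5, high_hz = 40, order = 6L) {
  stopifnot(inherits(epochs, "lpggnet_epochs"))
  fs <- epochs$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop_validation(sprintf(
      "band edges must satisfy 0 < low (%g) < high (%g) < fs/2 (%g)",
      low_hz, high_hz, fs / 2))
  d <- epochs$data
  dm <- dim(d)
  out <- d
  for (tr in seq_len(dm[1L]))
    for (ch in seq_len(dm[2L]))
      out[tr, ch, ] <- filter_trace_fft(d[tr, ch, ], fs, low_hz, high_hz, order)
  epoched_eeg(out, fs, epochs$labels, epochs$channel_names, epochs$class_names)
}

#' Z-score normalization
#'
#' Standardizes each (trial, channel) trace to mean 0 and standard
#' deviation 1 over time (default), or each channel over all trials and
#' samples jointly (`scope = "channel"`). The per-trial scope targets
#' trial-to-trial amplitude variability; the output is invariant to an
#' affine rescaling of the input trace.
#'
#' @param epochs an `lpggnet_epochs`.
#' @param scope `"trial"` (default) or `"channel"`.
#' @return A standardized `lpggnet_epochs`.
#' @export
eeg_zscore <- function(epochs, scope = c("trial", "channel")) {
  stopifnot(inherits(epochs, "lpggnet_epochs"))
  scope <- match.arg(scope)
  d <- epochs$data
  dm <- dim(d)
  if (scope == "trial") {
    for (tr in seq_len(dm[1L])) {
      for (ch in seq_len(dm[2L])) {
        x <- d[tr, ch, ]
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0)
          stop_numeric(sprintf(
            "zero-variance trace at trial %d, channel %s",
            tr, epochs$channel_names[ch]),
            data = list(trial = tr, channel = epochs$channel_names[ch]))
        d[tr, ch, ] <- (x - mean(x)) / s
      }
    }
  } else {
    for (ch in seq_len(dm[2L])) {
      x <- d[, ch, ]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0)
        stop_numeric(sprintf("zero-variance channel %s",
                             epochs$channel_names[ch]),
                     data = list(channel = epochs$channel_names[ch]))
      d[, ch, ] <- (x - mean(x)) / s
    }
  }
  epoched_eeg(d, epochs$fs, epochs$labels, epochs$channel_names,
              epochs$class_names)
}

#' Standard preprocessing pipeline
#'
#' Band-pass (0.5-40 Hz, zero-phase order-6 Butterworth) followed by
#' per-trial, per-channel z-scoring — the offline conditioning applied
#' before connectivity estimation and decoding.
#'
#' @param epochs an `lpggnet_epochs`.
#' @param low_hz,high_hz band edges in Hz.
#' @param order filter order.
#' @param zscore_scope passed to [eeg_zscore()].
#' @return A preprocessed `lpggnet_epochs`.
#' @export
preprocess <- function(epochs, low_hz = 0.5, high_hz = 40, order = 6L,
                       zscore_scope = "trial") {
  eeg_zscore(eeg_bandpass(epochs, low_hz, high_hz, order),
             scope = zscore_scope)
}
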