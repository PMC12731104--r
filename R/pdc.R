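# Multivariate autoregressive (MVAR) modelling and partial directed
# coherence (PDC).
#
# PDC follows the standard source-normalized definition: with the spectral
# coefficient matrix
#   Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs),
# the directed influence of source channel j on sink channel i at
# frequency f is
#   PDC_ij(f) = |Abar_ij(f)| / sqrt(sum_m |Abar_mj(f)|^2),
# i.e. each *column* (source) is normalized by its total outflow, so
# sum_i PDC_ij^2 = 1 at every frequency and PDC is in [0, 1].

#' Fit an MVAR model to a single trial (or pooled data matrix)
#'
#' Least-squares estimation of lag coefficient matrices from one trial:
#' each channel at time t is regressed on all channels at lags 1..p, pooling
#' all admissible time points of the trial.
#'
#' @param x channels x samples numeric matrix (one trial).
#' @param order model order p (>= 1).
#' @return A list of class `lpggnet_mvar`: `order`, `coeffs` (list of p
#'   N x N lag matrices; entry (i, j) of lag r couples channel j at t-r into
#'   channel i at t), `innovation_cov` (N x N residual covariance),
#'   `channel_names`.
#' @export
fit_mvar_trial <- function(x, order = 5L) {
  x <- as.matrix(x)
  n_ch <- nrow(x)
  n_s <- ncol(x)
  order <- as.integer(order)
  if (order < 1L) stop_validation("MVAR order must be >= 1")
  if (n_s <= order + n_ch)
    stop_validation(sprintf(
      "trial too short for MVAR: %d samples, need > order (%d) + channels (%d)",
      n_s, order, n_ch))
  tpts <- (order + 1L):n_s
  # regressors: rows = time points, cols = (lag 1 chans, lag 2 chans, ...)
  reg <- matrix(0, length(tpts), n_ch * order)
  for (r in seq_len(order))
    reg[, ((r - 1L) * n_ch + 1L):(r * n_ch)] <- t(x[, tpts - r, drop = FALSE])
  y <- t(x[, tpts, drop = FALSE])
  qr_reg <- qr(reg)
  if (qr_reg$rank < ncol(reg))
    stop_numeric("rank-deficient MVAR regressor matrix")
  beta <- qr.coef(qr_reg, y)                    # (N*p) x N
  resid <- y - reg %*% beta
  coeffs <- lapply(seq_len(order), function(r)
    t(beta[((r - 1L) * n_ch + 1L):(r * n_ch), , drop = FALSE]))
  sigma <- crossprod(resid) / (length(tpts) - n_ch * order)
  structure(list(order = order, coeffs = coeffs,
                 innovation_cov = sigma,
                 channel_names = rownames(x)),
            class = "lpggnet_mvar")
}

#' Fit per-trial MVAR models to epoched EEG
#'
#' @param epochs an `lpggnet_epochs`.
#' @param order model order p.
#' @return A list of `lpggnet_mvar`, one per trial.
#' @export
fit_mvar <- function(epochs, order = 5L) {
  stopifnot(inherits(epochs, "lpggnet_epochs"))
  lapply(seq_len(n_trials(epochs)), function(tr) {
    x <- epochs$data[tr, , ]
    rownames(x) <- epochs$channel_names
    fit_mvar_trial(x, order)
  })
}

#' Partial directed coherence of an MVAR model
#'
#' @param model an `lpggnet_mvar`.
#' @param freqs frequency grid in Hz, inside (0, fs/2].
#' @param fs sampling rate in Hz.
#' @return A list of class `lpggnet_pdc`: `freqs` and `values`, an
#'   N x N x n_freqs array with entry (i, j, f) = influence j -> i.
#' @export
pdc <- function(model, freqs, fs) {
  stopifnot(inherits(model, "lpggnet_mvar"))
  if (any(freqs <= 0 | freqs > fs / 2))
    stop_validation("freqs must lie in (0, fs/2]")
  n_ch <- nrow(model$coeffs[[1L]])
  vals <- array(NA_real_, c(n_ch, n_ch, length(freqs)))
  for (k in seq_along(freqs)) {
    abar <- diag(1 + 0i, n_ch)
    for (r in seq_len(model$order))
      abar <- abar - model$coeffs[[r]] * exp(-2i * pi * freqs[k] * r / fs)
    mod2 <- Mod(abar)^2
    colnorm <- sqrt(colSums(mod2))
    if (any(colnorm < .Machine$double.eps^0.5))
      stop_numeric(sprintf(
        "numerically degenerate spectral coefficient column at %g Hz",
        freqs[k]))
    vals[, , k] <- sweep(Mod(abar), 2L, colnorm, "/")
  }
  nm <- model$channel_names
  if (!is.null(nm)) dimnames(vals) <- list(nm, nm, NULL)
  structure(list(freqs = freqs, values = vals), class = "lpggnet_pdc")
}

#' Band-averaged PDC of a single model
#' @param p an `lpggnet_pdc`.
#' @param band length-2 numeric (low, high) in Hz.
#' @return N x N matrix of PDC values averaged over grid frequencies in band.
#' @export
pdc_band_mean <- function(p, band) {
  sel <- p$freqs >= band[1L] & p$freqs <= band[2L]
  if (!any(sel)) stop_validation("no grid frequencies inside the band")
  apply(p$values[, , sel, drop = FALSE], c(1L, 2L), mean)
}

#' Trial-averaged PDC adjacency
#'
#' Fits a per-trial MVAR model, computes PDC on a uniform 1 Hz grid, averages
#' over the requested band (default 8-30 Hz, the mu + beta range) and over
#' trials, zeroes the diagonal and applies self-looped symmetric
#' normalization `Dt^(-1/2) (A + I) Dt^(-1/2)` with `Dt` the row sums of
#' `A + I`. The averaged PDC matrix is directed; set `symmetrize = TRUE` to
#' average it with its transpose before normalizing.
#'
#' @param epochs an `lpggnet_epochs` (preprocessed).
#' @param order MVAR order (default 5).
#' @param band numeric length 2, Hz.
#' @param freq_step grid step in Hz.
#' @param symmetrize average A with t(A) before normalization.
#' @return An `lpggnet_adjacency` (see [adjacency_matrix()]), normalized.
#' @export
pdc_adjacency <- function(epochs, order = 5L, band = c(8, 30),
                          freq_step = 1, symmetrize = FALSE) {
  stopifnot(inherits(epochs, "lpggnet_epochs"))
  if (n_trials(epochs) < 1L) stop_validation("need at least one trial")
  if (band[1L] >= band[2L]) stop_validation("empty frequency band")
  freqs <- seq(band[1L], band[2L], by = freq_step)
  models <- fit_mvar(epochs, order)
  acc <- 0
  for (m in models)
    acc <- acc + pdc_band_mean(pdc(m, freqs, epochs$fs), band)
  a <- acc / length(models)
  diag(a) <- 0
  if (symmetrize) a <- (a + t(a)) / 2
  sym_normalize(adjacency_matrix(a, labels = epochs$channel_names,
                                 directed = !symmetrize))
}
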