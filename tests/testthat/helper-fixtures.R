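# Shared fixtures, built once per test run and memoized.
#
# Scale notes: simulations and trainings run at "desk scale" (128 Hz, 2 s
# trials, tens of trials, reduced widths/kernels) so the whole suite stays
# inside a small CPU budget; the generator's scientific structure (class
# balance, ERD topography, 1/f background, coupling) is unchanged.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small 4-class session on the full 22-channel montage
sim_small <- function(seed, runs = 3L, snr = 4, fs = 128, duration_s = 2,
                      trials_per_class = 8L, coupling = NULL) {
  simulate_session(sim_config(fs = fs, duration_s = duration_s,
                              trials_per_class = trials_per_class,
                              runs = runs, snr = snr, erd_depth = 0.6,
                              coupling = coupling, seed = seed))$epochs
}

# preprocessed high-SNR train/test pair used by the learning tests
fixture_train_epochs <- function()
  memo("train_epochs", preprocess(sim_small(11L, runs = 3L)))

fixture_test_epochs <- function()
  memo("test_epochs", preprocess(sim_small(99L, runs = 2L)))

# reduced model configuration matched to the 2 s x 128 Hz fixtures
reduced_config <- function()
  lpggnet_config(kernel1_len = 33L, kernel2_len = 13L,
                 conv_channels = c(4L, 8L), gcn_hidden = 16L,
                 fc_hidden = 32L, dropout = 0.25)

reduced_train_config <- function(epochs = 30L)
  train_config(epochs = epochs, batch_size = 16L, seed = 7L)

# train (and memoize) one ablation variant on the shared fixtures
fixture_trained <- function(name) {
  memo(paste0("trained_", name), {
    spec <- switch(name,
                   ours = ablation_spec(TRUE, TRUE, TRUE),
                   local_only = ablation_spec(TRUE, FALSE, FALSE),
                   partition_only = ablation_spec(FALSE, TRUE, FALSE),
                   global_only = ablation_spec(FALSE, FALSE, TRUE))
    tc <- reduced_train_config()
    set.seed(tc$seed)
    model <- lpggnet_model(reduced_config(), montage_dataset_a(),
                           scheme_dataset_a(), n_samples = 256L,
                           ablation = spec)
    fit <- lpggnet_train(model, fixture_train_epochs(), tc, mvar_order = 4L)
    list(model = fit$model, history = fit$history,
         metrics = lpggnet_evaluate(fit$model, fixture_test_epochs()))
  })
}

# tiny 4-channel geometry for model-mechanics tests
tiny_montage <- function() {
  montage(c("A", "B", "C", "D"),
          rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0)))
}

tiny_scheme <- function() {
  partition_scheme(list(P1 = c("A", "B"), P2 = c("B", "C"),
                        P3 = c("C", "D"), P4 = c("D", "A")),
                   name = "tiny")
}

tiny_model <- function(n_samples = 64L, dropout = 0,
                       ablation = ablation_spec(), seed = 5L) {
  set.seed(seed)
  cfg <- lpggnet_config(kernel1_len = 9L, kernel2_len = 5L,
                        conv_channels = c(2L, 3L), gcn_hidden = 4L,
                        fc_hidden = 8L, dropout = dropout)
  model <- lpggnet_model(cfg, tiny_montage(), tiny_scheme(),
                         n_samples = n_samples, ablation = ablation)
  a <- matrix(runif(16), 4, 4) * 0.3
  diag(a) <- 0
  a <- (a + t(a)) / 2
  set_local_adjacency(model,
                      sym_normalize(adjacency_matrix(a, labels = c("A", "B", "C", "D"))))
}

# collect named gradients from a completed backward pass
tape_grads <- function(fp) {
  grads <- list()
  for (nd in fp$tape$nodes) {
    nm <- nd$param_name
    if (!is.null(nm) && !is.null(nd$grad))
      grads[[nm]] <- if (is.null(grads[[nm]])) nd$grad else grads[[nm]] + nd$grad
  }
  grads
}

# random stable VAR(p) coefficient list for PDC property tests
random_stable_var <- function(n_ch, order) {
  repeat {
    coeffs <- lapply(seq_len(order), function(r)
      matrix(stats::rnorm(n_ch^2, sd = 0.4 / order), n_ch, n_ch))
    comp <- matrix(0, n_ch * order, n_ch * order)
    comp[seq_len(n_ch), ] <- do.call(cbind, coeffs)
    if (order > 1L)
      comp[(n_ch + 1L):(n_ch * order), seq_len(n_ch * (order - 1L))] <-
        diag(n_ch * (order - 1L))
    if (max(Mod(eigen(comp, only.values = TRUE)$values)) < 0.95) break
  }
  structure(list(order = order, coeffs = coeffs,
                 innovation_cov = diag(n_ch), channel_names = NULL),
            class = "lpggnet_mvar")
}

# simulate a VAR process directly (oracle for fit_mvar)
simulate_var <- function(coeffs, n, burn = 200L) {
  n_ch <- nrow(coeffs[[1L]])
  p <- length(coeffs)
  x <- matrix(0, n_ch, n + burn)
  for (t in (p + 1L):(n + burn)) {
    acc <- stats::rnorm(n_ch)
    for (r in seq_len(p)) acc <- acc + coeffs[[r]] %*% x[, t - r]
    x[, t] <- acc
  }
  x[, (burn + 1L):(burn + n), drop = FALSE]
}
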