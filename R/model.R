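# The three-branch decoder.
#
#   local branch:      temporal block (two convs, pooled) -> one graph
#                      convolution over the PDC-derived normalized adjacency
#   partition branch:  per partition, Gaussian-median-distance graph filter
#                      -> temporal block (no pooling); overlapping channels
#                      fused by arithmetic averaging
#   global branch:     feature-wise concatenation of both streams -> two
#                      residual graph convolutions whose adjacency is
#                      recomputed every forward pass from cosine similarity
#   classifier:        flatten -> FC -> ReLU -> dropout -> FC -> softmax

#' Model architecture configuration
#'
#' Defaults are sized for 22-channel, 4 s x 250 Hz input and land the total
#' parameter count near 0.5 M. `partition_summary = "mean_time"` collapses
#' the fused partition features per node to one value per conv channel
#' (mean over time) before they enter the global module; `"none"` keeps the
#' full flattened features (the global graph layers then grow quadratically
#' in that width).
#'
#' @param n_classes number of classes (default 4).
#' @param kernel1_len,kernel2_len temporal kernel lengths (85, 30).
#' @param conv_channels integer length 2: filters of the two conv layers.
#' @param pool_len max-pool width in the local branch (default 2).
#' @param gcn_hidden width of the local graph convolution output.
#' @param fc_hidden width of the hidden fully connected layer.
#' @param dropout dropout probability in [0, 1).
#' @param K Chebyshev receptive field; fixed at 1.
#' @param partition_summary "mean_time" or "none".
#' @param negatives cosine-adjacency negative handling ("clamp" or "abs").
#' @param shared_global_adjacency reuse the first residual layer's adjacency
#'   in the second layer instead of recomputing it from that layer's input.
#' @return An object of class `lpggnet_config`.
#' @export
lpggnet_config <- function(n_classes = 4L, kernel1_len = 85L,
                           kernel2_len = 30L, conv_channels = c(8L, 16L),
                           pool_len = 2L, gcn_hidden = 64L, fc_hidden = 128L,
                           dropout = 0.5, K = 1L,
                           partition_summary = c("mean_time", "none"),
                           negatives = c("clamp", "abs"),
                           shared_global_adjacency = FALSE) {
  partition_summary <- match.arg(partition_summary)
  negatives <- match.arg(negatives)
  if (K != 1L)
    stop_validation("only the first-order (K = 1) Chebyshev update is supported")
  if (kernel1_len < 1L || kernel2_len < 1L)
    stop_validation("kernel lengths must be >= 1")
  if (dropout < 0 || dropout >= 1)
    stop_validation("dropout must be in [0, 1)")
  structure(list(n_classes = as.integer(n_classes),
                 kernel1_len = as.integer(kernel1_len),
                 kernel2_len = as.integer(kernel2_len),
                 conv_channels = as.integer(conv_channels),
                 pool_len = as.integer(pool_len),
                 gcn_hidden = as.integer(gcn_hidden),
                 fc_hidden = as.integer(fc_hidden),
                 dropout = dropout, K = 1L,
                 partition_summary = partition_summary,
                 negatives = negatives,
                 shared_global_adjacency = shared_global_adjacency),
            class = "lpggnet_config")
}

#' Ablation specification
#'
#' Switches mirroring the module/component ablation matrix: which of the
#' three branches are active, which local adjacency is used (PDC or absolute
#' Pearson correlation), which partition metric (GMD or inverse-square
#' distance), whether the electrode partitioning itself is applied (when
#' off, the partition branch runs on the whole montage as one partition),
#' and whether the global residual connection is kept.
#'
#' @param use_local,use_partition,use_global branch switches.
#' @param local_adjacency "pdc" or "pearson".
#' @param partition_metric "gmd" or "ised".
#' @param use_partitioning apply the 4-partition scheme (default TRUE).
#' @param use_residual keep the identity shortcut of the second global
#'   graph layer.
#' @return An object of class `lpggnet_ablation`.
#' @export
ablation_spec <- function(use_local = TRUE, use_partition = TRUE,
                          use_global = TRUE,
                          local_adjacency = c("pdc", "pearson"),
                          partition_metric = c("gmd", "ised"),
                          use_partitioning = TRUE, use_residual = TRUE) {
  local_adjacency <- match.arg(local_adjacency)
  partition_metric <- match.arg(partition_metric)
  if (!use_local && !use_partition && !use_global)
    stop_validation("at least one branch must be enabled")
  structure(list(use_local = use_local, use_partition = use_partition,
                 use_global = use_global, local_adjacency = local_adjacency,
                 partition_metric = partition_metric,
                 use_partitioning = use_partitioning,
                 use_residual = use_residual),
            class = "lpggnet_ablation")
}

conv_out_len <- function(t, k) t - k + 1L

# temporal-axis arithmetic for both branches
branch_lengths <- function(config, n_samples) {
  t1 <- conv_out_len(n_samples, config$kernel1_len)
  p1 <- t1 %/% config$pool_len
  t2 <- conv_out_len(p1, config$kernel2_len)
  p2 <- t2 %/% config$pool_len
  tp1 <- conv_out_len(n_samples, config$kernel1_len)
  tp2 <- conv_out_len(tp1, config$kernel2_len)
  if (t2 < 1L || tp2 < 1L)
    stop_validation("input too short for the configured kernels/pooling")
  list(local = c(t1 = t1, p1 = p1, t2 = t2, p2 = p2),
       partition = c(t1 = tp1, t2 = tp2))
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

new_bn_state <- function(c) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(c)
  e$running_var <- rep(1, c)
  e
}

init_temporal_block <- function(params, bn, prefix, config) {
  c1 <- config$conv_channels[1L]
  c2 <- config$conv_channels[2L]
  k1 <- config$kernel1_len
  k2 <- config$kernel2_len
  params[[paste0(prefix, "_conv1_w")]] <- glorot(k1, c1 * k1, c(c1, 1L, k1))
  params[[paste0(prefix, "_conv1_b")]] <- numeric(c1)
  params[[paste0(prefix, "_bn1_gamma")]] <- rep(1, c1)
  params[[paste0(prefix, "_bn1_beta")]] <- numeric(c1)
  params[[paste0(prefix, "_conv2_w")]] <- glorot(c1 * k2, c2 * k2,
                                                 c(c2, c1, k2))
  params[[paste0(prefix, "_conv2_b")]] <- numeric(c2)
  params[[paste0(prefix, "_bn2_gamma")]] <- rep(1, c2)
  params[[paste0(prefix, "_bn2_beta")]] <- numeric(c2)
  bn[[paste0(prefix, "_bn1")]] <- new_bn_state(c1)
  bn[[paste0(prefix, "_bn2")]] <- new_bn_state(c2)
  invisible(NULL)
}

#' Build an LPGGNet model
#'
#' Assembles parameter tensors, per-partition graph filters and the fusion
#' map for a given montage, partition scheme and input length. Parameter
#' initialization draws from the current R random number generator state:
#' seed it (`set.seed`) for reproducible models. The local-branch adjacency
#' is data dependent (trial-averaged PDC of the training set) and is
#' attached later by [set_local_adjacency()] or automatically by
#' [lpggnet_train()].
#'
#' @param config an `lpggnet_config`.
#' @param montage an `lpggnet_montage`.
#' @param scheme an `lpggnet_scheme` (default the built-in 22-channel one).
#' @param n_samples samples per trial the model will be applied to.
#' @param ablation an `lpggnet_ablation`.
#' @return An object of class `lpggnet_model` (reference semantics for
#'   parameters and batch-norm state).
#' @export
lpggnet_model <- function(config, montage, scheme = scheme_dataset_a(),
                          n_samples, ablation = ablation_spec()) {
  stopifnot(inherits(config, "lpggnet_config"),
            inherits(montage, "lpggnet_montage"))
  n_ch <- length(montage$channel_names)
  lens <- branch_lengths(config, n_samples)
  c2 <- config$conv_channels[2L]
  params <- new.env(parent = emptyenv())
  bn <- new.env(parent = emptyenv())

  # --- partition preparation -------------------------------------------
  partition_prep <- NULL
  fusion_map <- NULL
  if (ablation$use_partition) {
    if (ablation$use_partitioning) {
      validate_scheme(scheme, montage)
      parts <- scheme$partitions
    } else {
      parts <- list(ALL = montage$channel_names)
    }
    partition_prep <- lapply(parts, function(chs) {
      idx <- match(chs, montage$channel_names)
      coords <- montage$coords[idx, , drop = FALSE]
      adj <- if (ablation$partition_metric == "gmd") gmd_adjacency(coords)
             else ised_adjacency(coords)
      list(channels = chs, idx = idx,
           filter = gaussian_filter(adj)$operator)
    })
    union_ch <- unique(unlist(lapply(partition_prep, `[[`, "channels")))
    fused_order <- intersect(montage$channel_names, union_ch)
    if (ablation$use_local && length(fused_order) != n_ch)
      stop_validation(paste(
        "partition union must cover the whole montage when the local",
        "branch is active (node sets must match at fusion)"))
    fusion_map <- lapply(fused_order, function(ch) {
      hits <- list()
      for (p in seq_along(partition_prep)) {
        j <- match(ch, partition_prep[[p]]$channels)
        if (!is.na(j)) hits[[length(hits) + 1L]] <- list(part = p, idx = j)
      }
      hits
    })
    names(fusion_map) <- fused_order
  }

  # --- parameters --------------------------------------------------------
  need_tb_local <- ablation$use_local ||
    (ablation$use_global && !ablation$use_partition && !ablation$use_local)
  f_local <- as.integer(c2 * lens$local[["p2"]])
  if (need_tb_local)
    init_temporal_block(params, bn, "local", config)
  if (ablation$use_local) {
    params$local_gcn_w <- glorot(f_local, config$gcn_hidden,
                                 c(f_local, config$gcn_hidden))
    params$local_gcn_b <- numeric(config$gcn_hidden)
  }
  if (ablation$use_partition)
    for (p in seq_along(partition_prep))
      init_temporal_block(params, bn, paste0("part", p), config)

  f_part <- if (config$partition_summary == "mean_time") c2
            else as.integer(c2 * lens$partition[["t2"]])
  f_tb_summary <- if (config$partition_summary == "mean_time") c2
                  else f_local
  f_fuse <- 0L
  if (ablation$use_local) f_fuse <- f_fuse + config$gcn_hidden
  if (ablation$use_partition) f_fuse <- f_fuse + f_part
  if (f_fuse == 0L) f_fuse <- f_tb_summary        # global-only path
  f_fuse <- as.integer(f_fuse)

  if (ablation$use_global) {
    params$global_gcn1_w <- glorot(f_fuse, f_fuse, c(f_fuse, f_fuse))
    params$global_gcn1_b <- numeric(f_fuse)
    params$global_gcn2_w <- glorot(f_fuse, f_fuse, c(f_fuse, f_fuse))
    params$global_gcn2_b <- numeric(f_fuse)
  }

  f_flat <- as.integer(f_fuse * n_ch)
  params$fc1_w <- glorot(f_flat, config$fc_hidden,
                         c(f_flat, config$fc_hidden))
  params$fc1_b <- numeric(config$fc_hidden)
  params$fc2_w <- glorot(config$fc_hidden, config$n_classes,
                         c(config$fc_hidden, config$n_classes))
  params$fc2_b <- numeric(config$n_classes)

  structure(list(config = config, ablation = ablation, montage = montage,
                 scheme = scheme, n_samples = as.integer(n_samples),
                 n_channels = n_ch, channel_names = montage$channel_names,
                 lens = lens, f_fuse = f_fuse,
                 partition_prep = partition_prep, fusion_map = fusion_map,
                 params = params, bn = bn, adj_local = NULL),
            class = "lpggnet_model")
}

#' Attach the local-branch adjacency
#'
#' @param model an `lpggnet_model`.
#' @param adjacency a normalized `lpggnet_adjacency` over the model montage.
#' @return The model (modified; parameters share state with the input).
#' @export
set_local_adjacency <- function(model, adjacency) {
  stopifnot(inherits(model, "lpggnet_model"),
            inherits(adjacency, "lpggnet_adjacency"))
  if (!adjacency$normalized)
    stop_validation("local adjacency must be sym-normalized")
  if (!identical(adjacency$labels, model$channel_names))
    stop_validation("adjacency labels must match the montage order")
  model$adj_local <- adjacency$values
  model
}

#' Total trainable parameter count
#' @param model an `lpggnet_model`.
#' @return integer parameter count.
#' @export
param_count <- function(model) {
  sum(vapply(ls(model$params), function(nm) length(model$params[[nm]]), 1))
}

#' @export
print.lpggnet_model <- function(x, ...) {
  cat(sprintf("<lpggnet_model> %d channels, %d samples, %s params\n",
              x$n_channels, x$n_samples,
              format(param_count(x), big.mark = ",")))
  ab <- x$ablation
  cat(sprintf("  branches: local=%s partition=%s global=%s\n",
              ab$use_local, ab$use_partition, ab$use_global))
  invisible(x)
}

## ---- forward pass ---------------------------------------------------------

tb_forward <- function(tape, model, xnode, prefix, with_pool, training) {
  p <- model$params
  bn <- model$bn
  cfg <- model$config
  pn <- function(nm) ad_param_store(tape, p, paste0(prefix, "_", nm))
  z <- op_conv1d(xnode, pn("conv1_w"), pn("conv1_b"), tape)
  z <- op_batchnorm(z, pn("bn1_gamma"), pn("bn1_beta"),
                    bn[[paste0(prefix, "_bn1")]], training, tape)
  z <- op_relu(z, tape)
  if (with_pool) z <- op_maxpool_t(z, cfg$pool_len, tape)
  z <- op_conv1d(z, pn("conv2_w"), pn("conv2_b"), tape)
  z <- op_batchnorm(z, pn("bn2_gamma"), pn("bn2_beta"),
                    bn[[paste0(prefix, "_bn2")]], training, tape)
  z <- op_relu(z, tape)
  if (with_pool) z <- op_maxpool_t(z, cfg$pool_len, tape)
  z
}

# conv tensor (C, N, T, B) -> node features (C*T, N, B)
conv_to_nodes <- function(tape, z) {
  d <- dim(z$value)
  z <- op_aperm(z, c(1L, 3L, 2L, 4L), tape)
  op_reshape(z, c(d[1L] * d[3L], d[2L], d[4L]), tape)
}

# epochs array (B, N, T) -> conv tensor (1, N, T, B)
input_tensor <- function(x) {
  xt <- aperm(x, c(2L, 3L, 1L))
  dim(xt) <- c(1L, dim(xt))
  xt
}

forward_pass <- function(model, x, labels = NULL, training = FALSE) {
  cfg <- model$config
  ab <- model$ablation
  d <- dim(x)
  if (d[2L] != model$n_channels)
    stop_validation(sprintf("expected %d channels, got %d",
                            model$n_channels, d[2L]))
  if (d[3L] != model$n_samples)
    stop_validation(sprintf("expected %d samples, got %d",
                            model$n_samples, d[3L]))
  tape <- ad_tape()
  streams <- list()

  if (ab$use_local) {
    if (is.null(model$adj_local))
      stop_validation("local adjacency not set; call set_local_adjacency()")
    xin <- ad_const(tape, input_tensor(x))
    z <- tb_forward(tape, model, xin, "local", TRUE, training)
    z <- conv_to_nodes(tape, z)
    z <- op_graphmm_fixed(model$adj_local, z, tape)
    z <- op_linear(z, ad_param_store(tape, model$params, "local_gcn_w"),
                   ad_param_store(tape, model$params, "local_gcn_b"), tape)
    streams$local <- op_gelu(z, tape)
  }

  if (ab$use_partition) {
    parts_out <- vector("list", length(model$partition_prep))
    for (p in seq_along(model$partition_prep)) {
      prep <- model$partition_prep[[p]]
      xp <- x[, prep$idx, , drop = FALSE]              # (B, n_p, T)
      xf <- aperm(xp, c(2L, 3L, 1L))                   # (n_p, T, B)
      for (b in seq_len(d[1L]))
        xf[, , b] <- prep$filter %*% xf[, , b]
      dim(xf) <- c(1L, dim(xf))
      z <- tb_forward(tape, model, ad_const(tape, xf),
                      paste0("part", p), FALSE, training)
      parts_out[[p]] <- conv_to_nodes(tape, z)
    }
    fused <- op_fuse(parts_out, model$fusion_map, tape)
    if (cfg$partition_summary == "mean_time") {
      fd <- dim(fused$value)
      c2 <- cfg$conv_channels[2L]
      t2 <- fd[1L] %/% c2
      fused <- op_reshape(fused, c(c2, t2, fd[2L], fd[3L]), tape)
      fused <- op_aperm(fused, c(1L, 3L, 2L, 4L), tape)  # (C, N, T, B)
      fused <- op_mean_t(fused, tape)
    }
    streams$partition <- fused
  }

  if (length(streams) == 0L) {           # global-only: plain temporal block
    xin <- ad_const(tape, input_tensor(x))
    z <- tb_forward(tape, model, xin, "local", TRUE, training)
    streams$tb <- if (cfg$partition_summary == "mean_time")
      op_mean_t(z, tape) else conv_to_nodes(tape, z)
  }

  zfuse <- if (length(streams) > 1L)
    op_concat_features(unname(streams), tape) else streams[[1L]]

  if (ab$use_global) {
    a1 <- op_dynamic_adjacency(zfuse, cfg$negatives, tape)
    z1 <- op_graphmm_batched(a1, zfuse, tape)
    z1 <- op_linear(z1, ad_param_store(tape, model$params, "global_gcn1_w"),
                    ad_param_store(tape, model$params, "global_gcn1_b"), tape)
    z1 <- op_gelu(z1, tape)
    s2 <- op_add(zfuse, z1, tape)
    a2 <- if (cfg$shared_global_adjacency) a1
          else op_dynamic_adjacency(s2, cfg$negatives, tape)
    z2 <- op_graphmm_batched(a2, s2, tape)
    z2 <- op_linear(z2, ad_param_store(tape, model$params, "global_gcn2_w"),
                    ad_param_store(tape, model$params, "global_gcn2_b"), tape)
    z2 <- op_gelu(z2, tape)
    zout <- if (ab$use_residual) op_add(z2, zfuse, tape) else z2
  } else {
    zout <- zfuse
  }

  dz <- dim(zout$value)
  flat <- op_reshape(zout, c(dz[1L] * dz[2L], dz[3L]), tape)
  h <- op_linear(flat, ad_param_store(tape, model$params, "fc1_w"),
                 ad_param_store(tape, model$params, "fc1_b"), tape)
  h <- op_relu(h, tape)
  h <- op_dropout(h, cfg$dropout, training, tape)
  logits <- op_linear(h, ad_param_store(tape, model$params, "fc2_w"),
                      ad_param_store(tape, model$params, "fc2_b"), tape)

  res <- list(tape = tape, logits = logits,
              features = c(lapply(streams, ad_value),
                           list(fused = zfuse$value,
                                global_out = zout$value)))
  if (!is.null(labels)) {
    loss <- op_softmax_ce(logits, labels, tape)
    res$probs <- loss$probs
    res$ce_loss <- loss
  } else {
    z <- logits$value
    zmax <- apply(z, 2L, max)
    ez <- exp(sweep(z, 2L, zmax))
    res$probs <- sweep(ez, 2L, colSums(ez), "/")
  }
  res
}

#' Forward pass: class probabilities
#'
#' Runs the model in evaluation mode (batch-norm running statistics, no
#' dropout) and returns per-trial softmax probabilities.
#'
#' @param model a trained (or freshly built) `lpggnet_model` with its local
#'   adjacency attached if the local branch is active.
#' @param epochs an `lpggnet_epochs` (or a trials x channels x samples
#'   array) matching the model's channels and samples.
#' @param batch_size evaluation chunk size.
#' @return trials x n_classes matrix of probabilities (rows sum to 1).
#' @export
lpggnet_forward <- function(model, epochs, batch_size = 32L) {
  x <- if (inherits(epochs, "lpggnet_epochs")) epochs$data else epochs
  n <- dim(x)[1L]
  out <- matrix(NA_real_, n, model$config$n_classes)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    fp <- forward_pass(model, x[s:e, , , drop = FALSE], training = FALSE)
    out[s:e, ] <- t(fp$probs)
  }
  out
}

#' Predicted class ids
#' @param model an `lpggnet_model`.
#' @param epochs epochs or array.
#' @param batch_size evaluation chunk size.
#' @return integer vector of 0-based class predictions.
#' @export
lpggnet_predict <- function(model, epochs, batch_size = 32L) {
  max.col(lpggnet_forward(model, epochs, batch_size)) - 1L
}

#' Cross-entropy loss of probability scores
#'
#' Mean over trials of the negative log probability assigned to the true
#' class. Accepts probabilities (rows summing to 1).
#'
#' @param scores trials x n_classes probability matrix.
#' @param labels 0-based integer class labels.
#' @return scalar loss.
#' @export
ce_loss <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= ncol(scores)))
    stop_validation(sprintf("labels must lie in 0..%d", ncol(scores) - 1L))
  if (length(labels) != nrow(scores))
    stop_validation("one label per score row required")
  -mean(log(pmax(scores[cbind(seq_len(nrow(scores)), labels + 1L)], 1e-300)))
}
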