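# Stand-alone functional forms of the network building blocks. These are
# the same computations the model wires together on the autodiff tape,
# exposed on plain arrays for inspection, testing and composition.

#' Temporal convolution block
#'
#' Two successive valid 1-D convolutions along time (kernel lengths 85 and
#' 30 by default) with batch normalization and ReLU, and — in the pooled
#' (local-branch) variant — a max-pool after each convolution. Runs the
#' given model branch's parameters in evaluation or training mode.
#'
#' @param model an `lpggnet_model`.
#' @param x trials x nodes x samples array.
#' @param branch parameter prefix, e.g. `"local"` or `"part1"`.
#' @param with_pool apply max-pooling after each convolution.
#' @param training use batch statistics (TRUE) or running statistics.
#' @return Array conv_channels x nodes x time x trials.
#' @export
temporal_block <- function(model, x, branch = "local", with_pool = TRUE,
                           training = FALSE) {
  stopifnot(inherits(model, "lpggnet_model"))
  if (dim(x)[3L] < model$config$kernel1_len)
    stop_validation("input shorter than the first kernel")
  tape <- ad_tape()
  xin <- ad_const(tape, input_tensor(x))
  ad_value(tb_forward(tape, model, xin, branch, with_pool, training))
}

#' Graph convolution layer
#'
#' The first-order Chebyshev update `Z = GeLU(A X W + b)` where `A` is a
#' normalized adjacency, applied independently per trial.
#'
#' @param features trials x nodes x f_in array (or nodes x f_in matrix for
#'   a single trial).
#' @param adjacency normalized `lpggnet_adjacency` or bare matrix.
#' @param weights f_in x f_out matrix.
#' @param bias length f_out numeric (default 0).
#' @param activation `"gelu"` (default) or `"identity"` (pre-activation).
#' @return Same layout as `features` with f_out features.
#' @export
gcn_layer <- function(features, adjacency, weights, bias = NULL,
                      activation = c("gelu", "identity")) {
  activation <- match.arg(activation)
  a <- if (inherits(adjacency, "lpggnet_adjacency")) adjacency$values
       else as.matrix(adjacency)
  weights <- as.matrix(weights)
  if (is.null(bias)) bias <- numeric(ncol(weights))
  single <- is.matrix(features)
  if (single) features <- array(features, c(1L, dim(features)))
  d <- dim(features)
  if (d[2L] != nrow(a)) stop_validation("node counts do not match")
  if (d[3L] != nrow(weights)) stop_validation("feature width does not match W")
  out <- array(0, c(d[1L], d[2L], ncol(weights)))
  for (tr in seq_len(d[1L])) {
    z <- a %*% features[tr, , , drop = TRUE] %*% weights
    z <- sweep(z, 2L, bias, "+")
    out[tr, , ] <- if (activation == "gelu") z * stats::pnorm(z) else z
  }
  if (single) matrix(out[1L, , ], d[2L], ncol(weights)) else out
}

#' Fuse overlapping partition features
#'
#' Channels that belong to k partitions receive the arithmetic mean of
#' their k per-partition feature vectors; the result has one row per
#' distinct channel, ordered by montage (first-appearance) order.
#'
#' @param features named list (one element per partition) of
#'   trials x nodes_p x f arrays; each must carry the partition's channel
#'   names as `dimnames[[2]]`, or supply `channels`.
#' @param scheme the `lpggnet_scheme` the features came from.
#' @param channels optional list of channel-name vectors, one per
#'   partition, overriding dimnames.
#' @param order output channel order; defaults to first appearance across
#'   partitions.
#' @return trials x n_distinct_channels x f array with channel dimnames.
#' @export
partition_fuse <- function(features, scheme = NULL, channels = NULL,
                           order = NULL) {
  if (is.null(channels)) {
    if (!is.null(scheme)) channels <- scheme$partitions
    else channels <- lapply(features, function(f) dimnames(f)[[2L]])
  }
  if (any(vapply(channels, is.null, TRUE)))
    stop_validation("partition channel names are required for fusion")
  fl <- vapply(features, function(f) dim(f)[3L], 1L)
  if (length(unique(fl)) != 1L)
    stop_validation("feature lengths differ across partitions")
  if (is.null(order))
    order <- unique(unlist(channels, use.names = FALSE))
  n_tr <- dim(features[[1L]])[1L]
  out <- array(0, c(n_tr, length(order), fl[1L]))
  for (ci in seq_along(order)) {
    ch <- order[ci]
    hits <- 0L
    for (p in seq_along(features)) {
      j <- match(ch, channels[[p]])
      if (is.na(j)) next
      out[, ci, ] <- out[, ci, ] + features[[p]][, j, , drop = TRUE]
      hits <- hits + 1L
    }
    if (hits == 0L)
      stop_validation(sprintf("channel %s not present in any partition", ch))
    out[, ci, ] <- out[, ci, ] / hits
  }
  dimnames(out) <- list(NULL, order, NULL)
  out
}

#' Per-branch node features of a forward pass
#'
#' Runs the model in evaluation mode and returns the intermediate node
#' representations: local graph-convolution output, fused partition
#' features, the concatenated global input and the global output.
#'
#' @param model an `lpggnet_model` with adjacency attached as needed.
#' @param x trials x channels x samples array (or `lpggnet_epochs`).
#' @return List of features x nodes x trials arrays (elements present
#'   according to the ablation spec): `local`, `partition`, `fused`,
#'   `global_out`.
#' @export
lpggnet_features <- function(model, x) {
  if (inherits(x, "lpggnet_epochs")) x <- x$data
  fp <- forward_pass(model, x, training = FALSE)
  fp$features
}
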