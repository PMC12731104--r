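# Graph operators shared by the three branches: Gaussian-median-distance
# (GMD) adjacency with hard sparsification, the random-walk Laplacian
# partition filter, cosine-similarity adjacency, and the self-looped
# symmetric normalization used by first-order (K = 1) Chebyshev graph
# convolution.

#' Adjacency matrix container
#'
#' @param values square numeric matrix.
#' @param labels ordered node (channel) names; defaults to existing
#'   dimnames or V1..Vn.
#' @param directed logical flag.
#' @param self_loops logical flag (diagonal carries self connections).
#' @param normalized logical flag (already degree-normalized).
#' @return An object of class `lpggnet_adjacency`.
#' @export
adjacency_matrix <- function(values, labels = NULL, directed = FALSE,
                             self_loops = FALSE, normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop_validation("adjacency matrix must be square")
  if (!all(is.finite(values)))
    stop_validation("adjacency entries must be finite")
  if (is.null(labels))
    labels <- if (!is.null(rownames(values))) rownames(values)
              else paste0("V", seq_len(nrow(values)))
  if (anyDuplicated(labels)) stop_validation("node labels must be unique")
  if (length(labels) != nrow(values))
    stop_validation("labels length must match matrix dimension")
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, directed = directed,
                 self_loops = self_loops, normalized = normalized),
            class = "lpggnet_adjacency")
}

#' @export
print.lpggnet_adjacency <- function(x, ...) {
  cat(sprintf("<lpggnet_adjacency> %d nodes%s%s%s\n", length(x$labels),
              if (x$directed) ", directed" else "",
              if (x$self_loops) ", self-loops" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Self-looped symmetric normalization
#'
#' Computes `At = A + I`, `Dt_ii = sum_j At_ij`, and returns
#' `Dt^(-1/2) At Dt^(-1/2)` — the propagation operator of first-order
#' Chebyshev graph convolution. Degrees are at least 1 thanks to the added
#' self-loop, so the operation is defined for any nonnegative input.
#'
#' @param adjacency an `lpggnet_adjacency` or bare square matrix with
#'   nonnegative entries (diagonal conventionally 0; a nonzero diagonal is
#'   simply added to the self-loop).
#' @return A normalized `lpggnet_adjacency`.
#' @export
sym_normalize <- function(adjacency) {
  a <- if (inherits(adjacency, "lpggnet_adjacency")) adjacency$values
       else as.matrix(adjacency)
  if (any(a < 0))
    stop_validation("sym_normalize requires nonnegative entries (clamp first)")
  at <- a + diag(nrow(a))
  dt <- rowSums(at)
  inv_sqrt <- 1 / sqrt(dt)
  values <- at * (inv_sqrt %o% inv_sqrt)
  labels <- if (inherits(adjacency, "lpggnet_adjacency")) adjacency$labels
            else rownames(a)
  adjacency_matrix(values, labels = labels,
                   directed = if (inherits(adjacency, "lpggnet_adjacency"))
                     adjacency$directed else FALSE,
                   self_loops = TRUE, normalized = TRUE)
}

#' Gaussian-median-distance bandwidth
#'
#' `delta` is the median of the Euclidean distances over all unordered
#' electrode pairs of the given coordinates. It sets the bandwidth (and the
#' hard support cutoff) of the GMD adjacency; because delta scales linearly
#' with the coordinates, the resulting adjacency is scale invariant.
#'
#' @param coords n x 3 coordinate matrix (or an `lpggnet_montage`).
#' @return A list of class `lpggnet_gmd_params` with element `delta`.
#' @export
gmd_delta <- function(coords) {
  if (inherits(coords, "lpggnet_montage")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L)
    stop_validation("need at least 2 electrode positions")
  d <- stats::dist(coords)
  delta <- stats::median(d)
  if (!is.finite(delta) || delta <= 0)
    stop_numeric("degenerate geometry: median pairwise distance is 0")
  structure(list(delta = delta), class = "lpggnet_gmd_params")
}

#' Gaussian-median-distance adjacency
#'
#' Three-branch weight rule on pairwise distances d with bandwidth delta:
#' 0 if d > delta (hard sparsification), exp(-d^2/delta^2) if 0 < d <= delta,
#' and 1 if d = 0 (diagonal). Set `cutoff = FALSE` to keep the smooth
#' Gaussian tail beyond delta.
#'
#' @param coords n x 3 coordinate matrix with rownames, or an
#'   `lpggnet_montage`.
#' @param params optional `lpggnet_gmd_params`; computed from `coords` when
#'   missing.
#' @param cutoff apply the hard zero beyond delta (default TRUE).
#' @return A symmetric self-looped `lpggnet_adjacency`.
#' @export
gmd_adjacency <- function(coords, params = NULL, cutoff = TRUE) {
  if (inherits(coords, "lpggnet_montage")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (is.null(params)) params <- gmd_delta(coords)
  delta <- params$delta
  if (!is.finite(delta) || delta <= 0) stop_validation("delta must be > 0")
  d <- as.matrix(stats::dist(coords))
  a <- exp(-d^2 / delta^2)
  if (cutoff) a[d > delta] <- 0
  a[d == 0] <- 1
  adjacency_matrix(a, labels = rownames(coords), directed = FALSE,
                   self_loops = TRUE)
}

#' Inverse-square-distance adjacency (comparator)
#'
#' The classic inverse-square Euclidean distance weighting w_ij = 1/d_ij^2
#' with diagonal 1 and no support cutoff — retained only as the ablation
#' comparator for the GMD rule (it keeps many weak long-range links, so its
#' graph is denser).
#'
#' @param coords n x 3 coordinate matrix or `lpggnet_montage`.
#' @return A symmetric self-looped `lpggnet_adjacency`.
#' @export
ised_adjacency <- function(coords) {
  if (inherits(coords, "lpggnet_montage")) coords <- coords$coords
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0))
    stop_numeric("coincident electrodes: inverse-square weight undefined")
  a <- 1 / d^2
  diag(a) <- 1
  adjacency_matrix(a, labels = rownames(coords), directed = FALSE,
                   self_loops = TRUE)
}

#' Partition graph filter
#'
#' The random-walk Laplacian operator `F = Dout^(-1) L = I - Dout^(-1) A`
#' built from a self-looped nonnegative adjacency (Dout = diagonal of row
#' sums). F annihilates constant signals (rows sum to 0), i.e. it removes
#' each node's neighbourhood average — the graph analogue of a local
#' common-mode reference.
#'
#' @param adjacency an `lpggnet_adjacency` (typically from
#'   [gmd_adjacency()]).
#' @return A list of class `lpggnet_graph_filter` with `labels` and
#'   `operator` (N x N matrix).
#' @export
gaussian_filter <- function(adjacency) {
  stopifnot(inherits(adjacency, "lpggnet_adjacency"))
  a <- adjacency$values
  dout <- rowSums(a)
  if (any(dout <= 0))
    stop_numeric(sprintf("zero row degree at node(s): %s",
                         paste(adjacency$labels[dout <= 0], collapse = ", ")))
  f <- diag(nrow(a)) - a / dout
  dimnames(f) <- dimnames(a)
  structure(list(labels = adjacency$labels, operator = f),
            class = "lpggnet_graph_filter")
}

#' Apply a graph filter along the channel axis
#'
#' Computes `F %*% X` per trial and time sample. Accepts an
#' `lpggnet_epochs`, a channels x samples matrix, or a plain channel vector.
#' Channel names (when present) must match the filter labels in name and
#' order.
#'
#' @param filter an `lpggnet_graph_filter`.
#' @param x epochs, matrix, or vector.
#' @return Filtered object of the same shape/class.
#' @export
apply_filter <- function(filter, x) {
  stopifnot(inherits(filter, "lpggnet_graph_filter"))
  f <- filter$operator
  check_labels <- function(labels) {
    if (!identical(as.character(labels), as.character(filter$labels)))
      stop_validation("channel labels/order do not match the filter")
  }
  if (inherits(x, "lpggnet_epochs")) {
    check_labels(x$channel_names)
    d <- x$data
    for (tr in seq_len(dim(d)[1L]))
      d[tr, , ] <- f %*% d[tr, , ]
    return(epoched_eeg(d, x$fs, x$labels, x$channel_names, x$class_names))
  }
  if (is.matrix(x)) {
    if (nrow(x) != nrow(f))
      stop_validation("channel dimension does not match the filter")
    if (!is.null(rownames(x))) check_labels(rownames(x))
    return(f %*% x)
  }
  if (length(x) != nrow(f))
    stop_validation("channel dimension does not match the filter")
  as.numeric(f %*% x)
}

#' Cosine-similarity adjacency of node features
#'
#' Entry (i, j) is the cosine of the angle between feature rows i and j
#' (diagonal 1). Raw cosines lie in [-1, 1]; because the downstream
#' symmetric normalization needs nonnegative degrees, negative entries are
#' clamped to 0 by default (`negatives = "clamp"`) or replaced by their
#' absolute value (`negatives = "abs"`); `negatives = "none"` returns the
#' raw cosines.
#'
#' @param node_features N x F numeric matrix (rows = nodes).
#' @param negatives one of "clamp", "abs", "none".
#' @return An `lpggnet_adjacency` (symmetric, self_loops TRUE).
#' @export
cosine_adjacency <- function(node_features,
                             negatives = c("clamp", "abs", "none")) {
  negatives <- match.arg(negatives)
  x <- as.matrix(node_features)
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    bad <- which(norms == 0)
    nm <- if (!is.null(rownames(x))) rownames(x)[bad] else as.character(bad)
    stop_numeric(sprintf("zero-norm feature row(s): %s",
                         paste(nm, collapse = ", ")),
                 data = list(nodes = nm))
  }
  xn <- x / norms
  a <- tcrossprod(xn)
  a <- pmin(a, 1)          # guard rounding above 1
  a <- pmax(a, -1)
  a <- switch(negatives,
              clamp = pmax(a, 0),
              abs = abs(a),
              none = a)
  diag(a) <- 1
  adjacency_matrix(a, labels = rownames(x), directed = FALSE,
                   self_loops = TRUE)
}

#' Absolute Pearson correlation adjacency (comparator)
#'
#' Trial-averaged absolute Pearson correlation between channels, the
#' ablation alternative to the PDC-driven local adjacency. Diagonal zeroed
#' and symmetric normalization applied, mirroring [pdc_adjacency()].
#'
#' @param epochs an `lpggnet_epochs`.
#' @return A normalized `lpggnet_adjacency`.
#' @export
pearson_adjacency <- function(epochs) {
  stopifnot(inherits(epochs, "lpggnet_epochs"))
  n <- n_trials(epochs)
  acc <- 0
  for (tr in seq_len(n))
    acc <- acc + abs(stats::cor(t(epochs$data[tr, , ])))
  a <- acc / n
  diag(a) <- 0
  sym_normalize(adjacency_matrix(a, labels = epochs$channel_names))
}
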