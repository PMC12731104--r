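# Minimal reverse-mode automatic differentiation tape.
#
# The decoder needs gradients through temporal convolutions, batch
# normalization, max pooling, graph propagation and the dynamically
# recomputed cosine-similarity adjacency. No deep-learning framework is
# available in this stack, so the package carries its own tape: each op
# records a node holding the forward value, its parent nodes and a closure
# that maps the incoming gradient to parent gradients. Values are plain
# numeric arrays; heavy lifting is BLAS matrix multiplication.
#
# Conventions for tensor layouts:
#   conv tensors:  (C, N, T, B)  channels x nodes x time x batch
#   node features: (F, N, B)     features x nodes x batch
#   batched adjacency: (N, N, B)

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    requires = NULL) {
  if (is.null(requires))
    requires <- any(vapply(parents, function(p) p$requires, TRUE))
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$requires <- requires
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_const <- function(tape, value) ad_node(tape, value, requires = FALSE)

ad_param <- function(tape, value) ad_node(tape, value, requires = TRUE)

# parameter leaf bound to a named slot of a parameter store (environment);
# the name lets the trainer map tape gradients back to the store
ad_param_store <- function(tape, store, nm) {
  nd <- ad_param(tape, store[[nm]])
  nd$param_name <- nm
  nd
}

ad_value <- function(nd) nd$value

# Run the backward sweep from a scalar loss node; afterwards every node
# with requires = TRUE carries its gradient in $grad.
ad_backward <- function(tape, loss) {
  for (nd in tape$nodes) nd$grad <- NULL
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward) || !nd$requires) next
    pg <- nd$backward(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$requires || is.null(pg[[k]])) next
      p$grad <- if (is.null(p$grad)) pg[[k]] else p$grad + pg[[k]]
    }
  }
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

op_add <- function(a, b, tape) {
  ad_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

op_scale <- function(a, s, tape) {
  ad_node(tape, a$value * s, list(a), function(g) list(g * s))
}

op_relu <- function(a, tape) {
  mask <- a$value > 0
  ad_node(tape, a$value * mask, list(a), function(g) list(g * mask))
}

op_gelu <- function(a, tape) {
  x <- a$value
  phi <- stats::pnorm(x)
  ad_node(tape, x * phi, list(a),
          function(g) list(g * (phi + x * stats::dnorm(x))))
}

op_dropout <- function(a, p, training, tape) {
  if (!training || p <= 0) return(a)
  keep <- array(stats::rbinom(length(a$value), 1L, 1 - p) / (1 - p),
                dim = dim(a$value))
  ad_node(tape, a$value * keep, list(a), function(g) list(g * keep))
}

# broadcast-add a length-C bias along the first dimension of an array
op_add_bias <- function(x, b, tape) {
  d <- dim(x$value)
  val <- x$value + as.numeric(b$value)     # recycling over dim 1 (fastest)
  ad_node(tape, val, list(x, b), function(g) {
    gm <- g
    dim(gm) <- c(d[1L], prod(d[-1L]))
    list(g, rowSums(gm))
  })
}

## ---- shape ----------------------------------------------------------------

op_reshape <- function(a, newdim, tape) {
  old <- dim(a$value)
  v <- a$value
  dim(v) <- newdim
  ad_node(tape, v, list(a), function(g) {
    dim(g) <- old
    list(g)
  })
}

op_aperm <- function(a, perm, tape) {
  inv <- order(perm)
  ad_node(tape, aperm(a$value, perm), list(a),
          function(g) list(aperm(g, inv)))
}

# concatenate node-feature tensors (F_i, N, B) along the feature dim
op_concat_features <- function(parts, tape) {
  fs <- vapply(parts, function(p) dim(p$value)[1L], 1L)
  d <- dim(parts[[1L]]$value)
  out <- array(0, c(sum(fs), d[2L], d[3L]))
  off <- 0L
  for (p in parts) {
    fp <- dim(p$value)[1L]
    out[(off + 1L):(off + fp), , ] <- p$value
    off <- off + fp
  }
  ad_node(tape, out, parts, function(g) {
    res <- vector("list", length(parts))
    off <- 0L
    for (k in seq_along(parts)) {
      res[[k]] <- g[(off + 1L):(off + fs[k]), , , drop = FALSE]
      off <- off + fs[k]
    }
    res
  })
}

## ---- dense layers ---------------------------------------------------------

# node-shared linear map on (F_in, N, B): Y = t(W) X + b, W is F_in x F_out
op_linear <- function(x, w, b, tape) {
  d <- dim(x$value)
  xm <- x$value
  dim(xm) <- c(d[1L], prod(d[-1L]))
  y <- crossprod(w$value, xm) + as.numeric(b$value)
  dim(y) <- c(ncol(w$value), d[-1L])
  ad_node(tape, y, list(x, w, b), function(g) {
    gm <- g
    dim(gm) <- c(ncol(w$value), prod(d[-1L]))
    dx <- w$value %*% gm
    dim(dx) <- d
    list(dx, xm %*% t(gm), rowSums(gm))
  })
}

## ---- temporal convolution -------------------------------------------------

# valid 1-D convolution along time, weights shared across nodes.
# x: (C_in, N, T, B); w: (C_out, C_in, k); b: length C_out.
# Realized as one matrix product per lag (never materializing an im2col
# buffer): Y = sum_kk W[,,kk] %*% X[, , kk:(kk+Tout-1), ].
op_conv1d <- function(x, w, b, tape) {
  d <- dim(x$value)
  cin <- d[1L]; n <- d[2L]; tt <- d[3L]; bb <- d[4L]
  k <- dim(w$value)[3L]
  cout <- dim(w$value)[1L]
  if (tt < k)
    stop_validation(sprintf("input length %d shorter than kernel %d", tt, k))
  tout <- tt - k + 1L
  m <- n * tout * bb
  lag_slice <- function(kk) {
    xs <- x$value[, , kk:(kk + tout - 1L), , drop = FALSE]
    dim(xs) <- c(cin, m)
    xs
  }
  ym <- matrix(0, cout, m)
  for (kk in seq_len(k))
    ym <- ym + matrix(w$value[, , kk], cout, cin) %*% lag_slice(kk)
  ym <- ym + as.numeric(b$value)
  dim(ym) <- c(cout, n, tout, bb)
  ad_node(tape, ym, list(x, w, b), function(g) {
    gm <- g
    dim(gm) <- c(cout, m)
    dw <- array(0, c(cout, cin, k))
    dx <- if (x$requires) array(0, d) else NULL
    for (kk in seq_len(k)) {
      dw[, , kk] <- tcrossprod(gm, lag_slice(kk))
      if (x$requires) {
        dxs <- crossprod(matrix(w$value[, , kk], cout, cin), gm)
        dim(dxs) <- c(cin, n, tout, bb)
        dx[, , kk:(kk + tout - 1L), ] <-
          dx[, , kk:(kk + tout - 1L), , drop = FALSE] + dxs
      }
    }
    list(dx, dw, rowSums(gm))
  })
}

## ---- max pooling over time ------------------------------------------------

op_maxpool_t <- function(x, p, tape) {
  d <- dim(x$value)
  tout <- d[3L] %/% p
  if (tout < 1L) stop_validation("pooling width exceeds time length")
  xc <- x$value[, , seq_len(tout * p), , drop = FALSE]
  dim(xc) <- c(d[1L], d[2L], p, tout, d[4L])
  cur <- xc[, , 1L, , , drop = FALSE]
  dim(cur) <- c(d[1L], d[2L], tout, d[4L])
  arg <- array(1L, dim(cur))
  if (p > 1L) for (i in 2:p) {
    xi <- xc[, , i, , , drop = FALSE]
    dim(xi) <- dim(cur)
    m <- xi > cur
    cur[m] <- xi[m]
    arg[m] <- i
  }
  ad_node(tape, cur, list(x), function(g) {
    dxc <- array(0, c(d[1L], d[2L], p, tout, d[4L]))
    for (i in seq_len(p)) {
      gi <- g
      gi[arg != i] <- 0
      dxc[, , i, , ] <- gi
    }
    dim(dxc) <- c(d[1L], d[2L], p * tout, d[4L])
    dx <- array(0, d)
    dx[, , seq_len(p * tout), ] <- dxc
    list(dx)
  })
}

## ---- batch normalization --------------------------------------------------

# per-channel (first dim) normalization over all remaining dims.
# state: environment with running_mean / running_var, updated in training.
op_batchnorm <- function(x, gamma, beta, state, training, tape,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  cdim <- d[1L]
  m <- prod(d[-1L])
  xm <- x$value
  dim(xm) <- c(cdim, m)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm^2) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * m / max(1, m - 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  sg <- sqrt(va + eps)
  xhat <- (xm - mu) / sg
  y <- gamma$value * xhat + beta$value
  dim(y) <- d
  ad_node(tape, y, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(cdim, m)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    if (training) {
      dx <- (gamma$value / sg) *
        (gm - dbeta / m - xhat * (dgamma / m))
    } else {
      dx <- gm * (gamma$value / sg)
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

## ---- graph propagation ----------------------------------------------------

# fixed adjacency: Y[,,b] = X[,,b] %*% t(A); A is a constant N x N matrix
op_graphmm_fixed <- function(a_mat, x, tape) {
  d <- dim(x$value)
  xp <- aperm(x$value, c(2L, 1L, 3L))      # (N, F, B)
  dim(xp) <- c(d[2L], d[1L] * d[3L])
  y <- a_mat %*% xp
  dim(y) <- c(d[2L], d[1L], d[3L])
  y <- aperm(y, c(2L, 1L, 3L))
  ad_node(tape, y, list(x), function(g) {
    gp <- aperm(g, c(2L, 1L, 3L))
    dim(gp) <- c(d[2L], d[1L] * d[3L])
    dx <- crossprod(a_mat, gp)
    dim(dx) <- c(d[2L], d[1L], d[3L])
    list(aperm(dx, c(2L, 1L, 3L)))
  })
}

# batched adjacency (N, N, B), batched features (F, N, B)
op_graphmm_batched <- function(a, x, tape) {
  d <- dim(x$value)
  bb <- d[3L]
  y <- array(0, d)
  for (b in seq_len(bb))
    y[, , b] <- x$value[, , b] %*% t(a$value[, , b])
  ad_node(tape, y, list(a, x), function(g) {
    da <- array(0, dim(a$value))
    dx <- array(0, d)
    for (b in seq_len(bb)) {
      gb <- g[, , b]
      da[, , b] <- crossprod(gb, x$value[, , b])
      dx[, , b] <- gb %*% a$value[, , b]
    }
    list(da, dx)
  })
}

## ---- dynamic cosine adjacency --------------------------------------------

# column-normalize node features (F, N, B): u = v / ||v||
op_colnorm <- function(x, tape) {
  d <- dim(x$value)
  xm <- x$value
  dim(xm) <- c(d[1L], d[2L] * d[3L])
  nrm <- sqrt(colSums(xm^2))
  if (any(nrm == 0)) stop_numeric("zero-norm node feature vector")
  u <- sweep(xm, 2L, nrm, "/")
  uv <- u
  dim(uv) <- d
  ad_node(tape, uv, list(x), function(g) {
    gm <- g
    dim(gm) <- c(d[1L], d[2L] * d[3L])
    dots <- colSums(u * gm)
    dx <- sweep(gm - sweep(u, 2L, dots, "*"), 2L, nrm, "/")
    dim(dx) <- d
    list(dx)
  })
}

# gram matrices of unit columns: A[,,b] = t(U_b) U_b  (cosine similarities)
op_gram <- function(u, tape) {
  d <- dim(u$value)
  bb <- d[3L]
  a <- array(0, c(d[2L], d[2L], bb))
  for (b in seq_len(bb)) a[, , b] <- crossprod(u$value[, , b])
  ad_node(tape, a, list(u), function(g) {
    du <- array(0, d)
    for (b in seq_len(bb))
      du[, , b] <- u$value[, , b] %*% (g[, , b] + t(g[, , b]))
    list(du)
  })
}

# clamp cosines into [0, 1] (or take |.|) and pin the diagonal at 1
op_cos_postprocess <- function(a, negatives, tape) {
  v <- a$value
  d <- dim(v)
  diag_mask <- array(FALSE, d)
  for (b in seq_len(d[3L])) diag_mask[, , b][cbind(1:d[1L], 1:d[1L])] <- TRUE
  if (negatives == "clamp") {
    inside <- v > 0 & v < 1
    out <- pmin(pmax(v, 0), 1)
    out[diag_mask] <- 1
    ad_node(tape, out, list(a), function(g) {
      g2 <- g * inside
      g2[diag_mask] <- 0
      list(g2)
    })
  } else {                                  # "abs"
    s <- sign(v)
    out <- pmin(abs(v), 1)
    inside <- abs(v) < 1
    out[diag_mask] <- 1
    ad_node(tape, out, list(a), function(g) {
      g2 <- g * s * inside
      g2[diag_mask] <- 0
      list(g2)
    })
  }
}

# batched self-looped symmetric normalization of nonnegative adjacency:
# At = A + I, s = rowSums(At), out = At / sqrt(s s^T)
op_symnorm_batched <- function(a, tape) {
  d <- dim(a$value)
  bb <- d[3L]
  out <- array(0, d)
  ss <- matrix(0, d[1L], bb)
  for (b in seq_len(bb)) {
    at <- a$value[, , b] + diag(d[1L])
    s <- rowSums(at)
    ss[, b] <- s
    ir <- 1 / sqrt(s)
    out[, , b] <- at * (ir %o% ir)
  }
  ad_node(tape, out, list(a), function(g) {
    da <- array(0, d)
    for (b in seq_len(bb)) {
      s <- ss[, b]
      gb <- g[, , b]
      ob <- out[, , b]
      u <- rowSums(gb * ob)               # sum_j G_kj out_kj
      v <- colSums(gb * ob)               # sum_i G_il out_il
      da[, , b] <- gb / sqrt(s %o% s) -
        0.5 * ((u / s) %o% rep(1, d[1L])) -
        0.5 * (rep(1, d[1L]) %o% (v / s))
    }
    list(da)
  })
}

# full dynamic adjacency from node features (F, N, B):
# cosine similarity -> negatives handling -> self-looped sym normalization
op_dynamic_adjacency <- function(x, negatives, tape) {
  u <- op_colnorm(x, tape)
  a <- op_gram(u, tape)
  a <- op_cos_postprocess(a, negatives, tape)
  op_symnorm_batched(a, tape)
}

## ---- fusion and reductions ------------------------------------------------

# average feature copies of channels shared across partitions.
# parts: list of (F, n_p, B) nodes; map: list over output channels of
# data.frame-ish list(part = integer, idx = integer) pairs.
op_fuse <- function(parts, map, tape) {
  d1 <- dim(parts[[1L]]$value)
  n_out <- length(map)
  out <- array(0, c(d1[1L], n_out, d1[3L]))
  for (c in seq_len(n_out)) {
    entries <- map[[c]]
    acc <- 0
    for (e in entries)
      acc <- acc + parts[[e$part]]$value[, e$idx, , drop = FALSE]
    out[, c, ] <- acc / length(entries)
  }
  ad_node(tape, out, parts, function(g) {
    grads <- lapply(parts, function(p) array(0, dim(p$value)))
    for (c in seq_len(n_out)) {
      entries <- map[[c]]
      share <- g[, c, , drop = FALSE] / length(entries)
      for (e in entries)
        grads[[e$part]][, e$idx, ] <- grads[[e$part]][, e$idx, , drop = FALSE] + share
    }
    grads
  })
}

# mean over the time axis of a conv tensor: (C, N, T, B) -> (C, N, B)
op_mean_t <- function(x, tape) {
  d <- dim(x$value)
  y <- colMeans(aperm(x$value, c(3L, 1L, 2L, 4L)))   # mean over T
  dim(y) <- c(d[1L], d[2L], d[4L])
  ad_node(tape, y, list(x), function(g) {
    gv <- g / d[3L]
    dim(gv) <- c(d[1L], d[2L], d[4L])
    out <- array(0, d)
    for (t in seq_len(d[3L])) out[, , t, ] <- gv
    list(out)
  })
}

## ---- loss -----------------------------------------------------------------

# numerically stable softmax + mean cross-entropy; logits (K, B),
# labels 0-based integer vector of length B.
op_softmax_ce <- function(logits, labels, tape) {
  z <- logits$value
  k <- nrow(z)
  bb <- ncol(z)
  zmax <- apply(z, 2L, max)
  ez <- exp(sweep(z, 2L, zmax))
  p <- sweep(ez, 2L, colSums(ez), "/")
  idx <- cbind(as.integer(labels) + 1L, seq_len(bb))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  nd <- ad_node(tape, loss, list(logits), function(g) {
    y <- matrix(0, k, bb)
    y[idx] <- 1
    list(g * (p - y) / bb)
  })
  nd$probs <- p
  nd
}
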