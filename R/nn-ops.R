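# Differentiable operations on (C, X, Y, Z) arrays.
#
# Dense conv weights are stored as a (Cin * k^3) x Cout matrix, the
# column-major flattening of an array dim c(k, k, k, Cin, Cout); depthwise
# weights as an array dim c(C, k, k, k).

op_conv3d <- function(x, w, k, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                      bias = NULL) {
  xv <- x$value
  y <- cpp_conv3d_fw(xv, dim(xv), w$value, k, cout, stride, pad)
  if (!is.null(bias)) {
    y <- y + array(rep(bias$value, length.out = length(y)), dim = dim(y))
    parents <- list(x, w, bias)
    backward <- function(dy) {
      g <- cpp_conv3d_bw(xv, dim(xv), w$value, k, cout, stride, pad, dy)
      db <- rowSums(matrix(dy, nrow = cout))
      list(g$dx, g$dw, db)
    }
    return(ag_node(y, parents, backward))
  }
  ag_node(y, list(x, w), function(dy) {
    g <- cpp_conv3d_bw(xv, dim(xv), w$value, k, cout, stride, pad, dy)
    list(g$dx, g$dw)
  })
}

op_dwconv3d <- function(x, w, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  xv <- x$value
  y <- cpp_dwconv3d_fw(xv, dim(xv), w$value, k, stride, pad)
  ag_node(y, list(x, w), function(dy) {
    g <- cpp_dwconv3d_bw(xv, dim(xv), w$value, k, stride, pad, dy)
    list(g$dx, g$dw)
  })
}

op_relu <- function(x) {
  keep <- x$value > 0
  ag_node(x$value * keep, list(x), function(dy) list(dy * keep))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(dy) list(dy * s * (1 - s)))
}

op_add <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is_ag_node(xs[[1]])) xs <- xs[[1]]
  v <- xs[[1]]$value
  for (i in seq_along(xs)[-1]) v <- v + xs[[i]]$value
  ag_node(v, xs, function(dy) rep(list(dy), length(xs)))
}

# Scale every channel of x by a scalar weight (w has length C).
op_scale_channels <- function(x, w) {
  xv <- x$value
  C <- dim(xv)[1]
  y <- xv * as.vector(w$value)  # recycles along the fastest (channel) axis
  ag_node(y, list(x, w), function(dy) {
    dw <- rowSums(matrix(dy * xv, nrow = C))
    list(dy * as.vector(w$value), dw)
  })
}

op_concat_channels <- function(xs) {
  vals <- lapply(xs, function(n) n$value)
  cs <- vapply(vals, function(v) dim(v)[1], integer(1))
  sp <- dim(vals[[1]])[-1]
  y <- array(0, dim = c(sum(cs), sp))
  off <- 0L
  for (i in seq_along(vals)) {
    y[off + seq_len(cs[i]), , , ] <- vals[[i]]
    off <- off + cs[i]
  }
  ag_node(y, xs, function(dy) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- dy[off + seq_len(cs[i]), , , , drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

op_slice_channels <- function(x, idx) {
  xv <- x$value
  ag_node(xv[idx, , , , drop = FALSE], list(x), function(dy) {
    dx <- array(0, dim = dim(xv))
    dx[idx, , , ] <- dy
    list(dx)
  })
}

# Pure channel permutation: output channel i takes input channel perm[i].
op_permute_channels <- function(x, perm) {
  inv <- order(perm)
  ag_node(x$value[perm, , , , drop = FALSE], list(x),
          function(dy) list(dy[inv, , , , drop = FALSE]))
}

op_pool_mean <- function(x, f) {
  if (f == 1L) return(x)
  xv <- x$value
  ag_node(cpp_block_reduce(xv, dim(xv), f, TRUE), list(x),
          function(dy) list(cpp_block_expand(dy, dim(dy), f, 1 / f^3)))
}

op_upsample_nearest <- function(x, f) {
  if (f == 1L) return(x)
  xv <- x$value
  ag_node(cpp_block_expand(xv, dim(xv), f, 1), list(x),
          function(dy) list(cpp_block_reduce(dy, dim(dy), f, FALSE)))
}

# Global average pooling to a length-C vector.
op_gap <- function(x) {
  xv <- x$value
  C <- dim(xv)[1]
  n <- prod(dim(xv)[-1])
  ag_node(rowMeans(matrix(xv, nrow = C)), list(x), function(dy) {
    list(array(rep(dy / n, n), dim = dim(xv)))
  })
}

# 1-D convolution along the channel axis, one shared kernel of length k
# (odd), zero padding, applied independently at every voxel.
op_conv1d_channels <- function(x, w, k) {
  xv <- x$value
  C <- dim(xv)[1]
  half <- (k - 1L) %/% 2L
  wv <- w$value
  y <- array(0, dim = dim(xv))
  for (j in seq_len(k)) {
    src <- seq_len(C) + (j - 1L - half)
    ok <- src >= 1L & src <= C
    if (!any(ok)) next
    y[ok, , , ] <- y[ok, , , , drop = FALSE] + wv[j] * xv[src[ok], , , , drop = FALSE]
  }
  ag_node(y, list(x, w), function(dy) {
    dx <- array(0, dim = dim(xv))
    dw <- numeric(k)
    for (j in seq_len(k)) {
      src <- seq_len(C) + (j - 1L - half)
      ok <- src >= 1L & src <= C
      if (!any(ok)) next
      dx[src[ok], , , ] <- dx[src[ok], , , , drop = FALSE] + wv[j] * dy[ok, , , , drop = FALSE]
      dw[j] <- sum(dy[ok, , , , drop = FALSE] * xv[src[ok], , , , drop = FALSE])
    }
    list(dx, dw)
  })
}

# Group normalization over (channels-in-group x space), with affine terms.
op_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  xv <- x$value
  C <- dim(xv)[1]
  g <- min(groups, C)
  while (C %% g != 0L) g <- g - 1L
  cg <- C %/% g
  n <- prod(dim(xv)[-1])
  xm <- matrix(xv, nrow = C)
  xhat <- matrix(0, nrow = C, ncol = n)
  invstd <- numeric(g)
  for (j in seq_len(g)) {
    rows <- (j - 1L) * cg + seq_len(cg)
    mu <- mean(xm[rows, ])
    va <- mean((xm[rows, ] - mu)^2)
    invstd[j] <- 1 / sqrt(va + eps)
    xhat[rows, ] <- (xm[rows, ] - mu) * invstd[j]
  }
  y <- array(xhat * gamma$value + beta$value, dim = dim(xv))
  ag_node(y, list(x, gamma, beta), function(dy) {
    dym <- matrix(dy, nrow = C)
    dgamma <- rowSums(dym * xhat)
    dbeta <- rowSums(dym)
    dxhat <- dym * gamma$value
    dx <- matrix(0, nrow = C, ncol = n)
    m <- cg * n
    for (j in seq_len(g)) {
      rows <- (j - 1L) * cg + seq_len(cg)
      dh <- dxhat[rows, , drop = FALSE]
      xh <- xhat[rows, , drop = FALSE]
      s1 <- sum(dh)
      s2 <- sum(dh * xh)
      dx[rows, ] <- invstd[j] / m * (m * dh - s1 - xh * s2)
    }
    list(array(dx, dim = dim(xv)), dgamma, dbeta)
  })
}

# Combined soft-Dice + binary cross-entropy over the three region channels,
# taking logits. Returns a scalar node.
op_dice_bce_loss <- function(logits, target, eps = 1e-5) {
  lv <- logits$value
  C <- dim(lv)[1]
  p <- 1 / (1 + exp(-lv))
  tm <- target
  n <- length(lv) / C
  pm <- matrix(p, nrow = C)
  mm <- matrix(tm, nrow = C)
  inter <- rowSums(pm * mm)
  psum <- rowSums(pm)
  msum <- rowSums(mm)
  dice_c <- (2 * inter + eps) / (psum + msum + eps)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- -mean(tm * log(pc) + (1 - tm) * log(1 - pc))
  loss <- mean(1 - dice_c) + bce
  ag_node(loss, list(logits), function(dy) {
    # d(1 - dice_c)/dp then chain through the sigmoid; BCE through the
    # sigmoid is (p - t) / N.
    denom <- (psum + msum + eps)^2
    ddice_dp <- -(2 * mm * (psum + msum + eps) - (2 * inter + eps)) / denom / C
    dbce_dlogit <- (p - tm) / length(lv)
    dp <- array(ddice_dp, dim = dim(lv)) * p * (1 - p) + dbce_dlogit
    list(dy * dp)
  })
}
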