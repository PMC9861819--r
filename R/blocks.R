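# Building blocks of the multi-resolution backbone: channel split/shuffle,
# the cross-resolution weighting unit (CWU), the spatial weighting unit
# (SWU), the lightweight conditional channel weighting (LCC) block, and the
# lightweight multi-resolution fusion (LMRF) operators.
#
# Parameterised blocks are built by `new_*()` constructors which register
# their convolution layers in a build context so the complexity walker can
# account for every layer exactly as constructed.

new_build_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx$layers <- list()
  ctx
}

ctx_param <- function(ctx, name, value) {
  node <- ag_leaf(value)
  ctx$params[[name]] <- node
  node
}

ctx_layer <- function(ctx, name, kind, k, cin, cout, groups, stride,
                      extent_div, n_params, macs_per_voxel) {
  ctx$layers[[length(ctx$layers) + 1L]] <- tibble::tibble(
    layer = name, kind = kind, k = k, cin = cin, cout = cout,
    groups = groups, stride = stride, extent_div = extent_div,
    n_params = n_params, macs_per_voxel = macs_per_voxel
  )
}

init_dense_w <- function(k, cin, cout, init = "he") {
  n <- cin * k^3
  v <- if (init == "zero") numeric(n * cout) else rnorm(n * cout, sd = sqrt(2 / n))
  matrix(v, nrow = n, ncol = cout)
}

init_dw_w <- function(channels, k, init = "he") {
  n <- k^3
  v <- if (init == "zero") numeric(channels * n) else
    rnorm(channels * n, sd = sqrt(2 / n))
  array(v, dim = c(channels, k, k, k))
}

# Dense 3D convolution module, optionally followed by group norm + ReLU
# ("Conv Block" in the backbone tables).
new_conv3d <- function(cin, cout, k = 3L, stride = 1L, bias = FALSE,
                       norm = FALSE, act = FALSE, groups_norm = 8L,
                       extent_div = 1L, ctx = new_build_ctx(),
                       name = "conv", init = "he") {
  w <- ctx_param(ctx, paste0(name, ".w"), init_dense_w(k, cin, cout, init))
  b <- if (bias) ctx_param(ctx, paste0(name, ".b"), numeric(cout)) else NULL
  nb <- if (bias) cout else 0
  ctx_layer(ctx, name, "conv3d", k, cin, cout, 1L, stride, extent_div,
            k^3 * cin * cout + nb, k^3 * cin * cout)
  gamma <- beta <- NULL
  if (norm) {
    gamma <- ctx_param(ctx, paste0(name, ".gamma"), rep(1, cout))
    beta <- ctx_param(ctx, paste0(name, ".beta"), numeric(cout))
    ctx_layer(ctx, paste0(name, ".gn"), "group_norm", NA, cout, cout, NA, NA,
              extent_div, 2L * cout, 0)
  }
  mod <- list(kind = "conv3d", w = w, b = b, gamma = gamma, beta = beta,
              k = k, cin = cin, cout = cout, stride = stride,
              norm = norm, act = act, groups_norm = groups_norm)
  mod$forward <- function(x) {
    y <- op_conv3d(x, w, k, cout, stride = stride, bias = b)
    if (norm) y <- op_groupnorm(y, gamma, beta, groups_norm)
    if (act) y <- op_relu(y)
    y
  }
  mod
}

# Depthwise (channel-preserving) 3x3x3 convolution module.
new_dwconv3d <- function(channels, k = 3L, stride = 1L, extent_div = 1L,
                         ctx = new_build_ctx(), name = "dwconv", init = "he") {
  w <- ctx_param(ctx, paste0(name, ".w"), init_dw_w(channels, k, init))
  ctx_layer(ctx, name, "conv3d", k, channels, channels, channels, stride,
            extent_div, k^3 * channels, k^3 * channels)
  mod <- list(kind = "dwconv3d", w = w, k = k, channels = channels,
              stride = stride)
  mod$forward <- function(x) op_dwconv3d(x, w, k, stride = stride)
  mod
}

#' Adaptive kernel size for the channel-attention 1-D convolution
#'
#' Maps a channel count to the kernel size of the 1-D convolution that
#' learns per-channel weights in the cross-resolution weighting unit:
#' `floor(log2(C)/2 + 1/2)`, promoted to the next odd integer when even
#' (the adaptive-kernel rule of efficient channel attention).
#'
#' @param channels Positive integer channel count.
#' @return An odd positive integer kernel size, non-decreasing in `channels`.
#' @examples
#' cwu_kernel_size(16)   # 3
#' cwu_kernel_size(256)  # 5
#' @export
cwu_kernel_size <- function(channels) {
  if (!is.numeric(channels) || length(channels) != 1L || channels < 1)
    stop("`channels` must be a single integer >= 1", call. = FALSE)
  k <- floor(log2(channels) / 2 + 0.5)
  if (k %% 2 == 0) k <- k + 1
  as.integer(max(k, 1))
}

#' Split a feature map into two channel halves
#'
#' The first half of the channels feeds the weighted main path of the LCC
#' block; the second half passes through untouched. Concatenating the two
#' outputs in order reproduces the input.
#'
#' @param x Array of dim `(C, X, Y, Z)` with even `C` (or an internal graph
#'   node).
#' @return List with elements `main` and `identity`, each with `C/2` channels.
#' @export
channel_split <- function(x) {
  v <- node_value(x)
  C <- dim(v)[1]
  if (C %% 2 != 0) stop("channel count must be even for channel_split", call. = FALSE)
  if (is_ag_node(x)) {
    list(main = op_slice_channels(x, seq_len(C / 2)),
         identity = op_slice_channels(x, C / 2 + seq_len(C / 2)))
  } else {
    list(main = v[seq_len(C / 2), , , , drop = FALSE],
         identity = v[C / 2 + seq_len(C / 2), , , , drop = FALSE])
  }
}

shuffle_perm <- function(C, groups) {
  if (C %% groups != 0) stop("channel count not divisible by shuffle groups", call. = FALSE)
  o <- 0:(C - 1)
  g <- o %% groups
  i <- o %/% groups
  as.integer(g * (C / groups) + i + 1)
}

#' Interleave channel groups (channel shuffle)
#'
#' Permutes channels so that the channel at index `g*(C/groups) + i` moves
#' to index `i*groups + g` (0-based), mixing information between the two
#' concatenated halves of an LCC block.
#'
#' @param x Array of dim `(C, X, Y, Z)` (or an internal graph node).
#' @param groups Number of groups; must divide `C`.
#' @return The permuted feature map, same shape as `x`.
#' @export
channel_shuffle <- function(x, groups = 2L) {
  C <- dim(node_value(x))[1]
  perm <- shuffle_perm(C, groups)
  if (is_ag_node(x)) op_permute_channels(x, perm)
  else node_value(x)[perm, , , , drop = FALSE]
}

# ---- Cross-resolution weighting unit -------------------------------------

# The CWU pools its own split-half and the other branches' maps to the
# lowest resolution present, concatenates them, learns per-channel weights
# with a 1-D convolution along the channel axis (kernel from
# cwu_kernel_size), reduces spatially, applies a sigmoid, and rescales the
# own-half channels. The 1-D convolution acts identically at every voxel of
# the pooled grid, so it commutes exactly with the spatial reduction; it is
# applied at the pooled extent, matching the layer accounting of the
# backbone.
new_cwu <- function(own_channels, other_channels = integer(), extent_div = 1L,
                    min_extent_div = extent_div, ctx = new_build_ctx(),
                    name = "cwu", init = "he") {
  total <- own_channels + sum(other_channels)
  k <- cwu_kernel_size(total)
  wv <- if (init == "zero") numeric(k) else rnorm(k, sd = sqrt(1 / k))
  w <- ctx_param(ctx, paste0(name, ".w"), wv)
  ctx_layer(ctx, name, "conv1d_channel", k, total, total, 1L, 1L,
            min_extent_div, k, k * total)
  mod <- list(kind = "cwu", w = w, k = k, own_channels = own_channels,
              other_channels = other_channels, total = total)
  mod$forward <- function(own_half, other_maps = list()) {
    own_ext <- dim(node_value(own_half))[2]
    exts <- c(own_ext, vapply(other_maps, function(m) dim(node_value(m))[2],
                              numeric(1)))
    min_ext <- min(exts)
    pooled <- c(list(op_pool_mean(own_half, as.integer(own_ext / min_ext))),
                lapply(other_maps, function(m) {
                  e <- dim(node_value(m))[2]
                  op_pool_mean(m, as.integer(e / min_ext))
                }))
    cat_map <- if (length(pooled) > 1L) op_concat_channels(pooled) else pooled[[1]]
    conv <- op_conv1d_channels(cat_map, w, k)
    wvec <- op_gap(conv)                       # length `total`
    own_w <- ag_node(wvec$value[seq_len(own_channels)], list(wvec),
                     function(dy) {
                       g <- numeric(total)
                       g[seq_len(own_channels)] <- dy
                       list(g)
                     })
    own_w <- op_sigmoid_vec(own_w)
    op_scale_channels(own_half, own_w)
  }
  mod
}

# sigmoid on a plain vector node
op_sigmoid_vec <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(dy) list(dy * s * (1 - s)))
}

#' Cross-resolution channel weighting
#'
#' Pools the branch's own split-half together with the other branches' maps
#' to the lowest resolution present, learns per-channel weights through a
#' shared 1-D convolution along the channel axis followed by global average
#' pooling and a sigmoid, and rescales the own-half channels by the weight
#' slice aligned with them (own half first in the concatenation order).
#'
#' @param own_half Array `(C/2, X, Y, Z)`: the branch's main split-half.
#' @param other_maps List of arrays from the other branches of the stage
#'   (their full, pre-split maps), possibly empty at the first stage.
#' @param kernel Optional numeric kernel for the 1-D convolution (length
#'   `cwu_kernel_size(total channels)`); defaults to zeros, which yields
#'   weights of exactly 0.5 everywhere.
#' @return Array shaped like `own_half`, rescaled channel-wise.
#' @export
cwu_forward <- function(own_half, other_maps = list(), kernel = NULL) {
  oc <- dim(own_half)[1]
  others <- vapply(other_maps, function(m) dim(m)[1], integer(1))
  mod <- new_cwu(oc, others, init = "zero")
  if (!is.null(kernel)) {
    if (length(kernel) != mod$k)
      stop("kernel must have length cwu_kernel_size(total) = ", mod$k, call. = FALSE)
    mod$w$value <- as.numeric(kernel)
  }
  out <- with_no_grad(mod$forward(ag_leaf(own_half),
                                  lapply(other_maps, ag_leaf)))
  out$value
}

# ---- Spatial weighting unit ----------------------------------------------

new_swu <- function(channels, extent_div = 1L, ctx = new_build_ctx(),
                    name = "swu", init = "he") {
  w1 <- ctx_param(ctx, paste0(name, ".w1"), init_dense_w(1L, channels, channels, init))
  w2 <- ctx_param(ctx, paste0(name, ".w2"), init_dense_w(1L, channels, channels, init))
  # the two pointwise convolutions act on the globally pooled 1x1x1 map
  ctx_layer(ctx, paste0(name, ".fc1"), "conv3d", 1L, channels, channels, 1L, 1L,
            NA, channels^2, channels^2)
  ctx_layer(ctx, paste0(name, ".fc2"), "conv3d", 1L, channels, channels, 1L, 1L,
            NA, channels^2, channels^2)
  mod <- list(kind = "swu", w1 = w1, w2 = w2, channels = channels)
  mod$forward <- function(x) {
    g <- op_gap(x)                              # length C
    h <- ag_matvec(w1, g, transpose = TRUE)     # C -> C
    h <- ag_node(pmax(h$value, 0), list(h), function(dy) list(dy * (h$value > 0)))
    wv <- ag_matvec(w2, h, transpose = TRUE)
    wv <- op_sigmoid_vec(wv)
    op_scale_channels(x, wv)
  }
  mod
}

# y = t(W) %*% v for a (Cin x Cout) weight matrix (pointwise conv on a
# 1x1x1 map).
ag_matvec <- function(w, v, transpose = TRUE) {
  wv <- w$value
  y <- as.vector(crossprod(wv, v$value))
  ag_node(y, list(w, v), function(dy) {
    list(outer(as.vector(v$value), dy), as.vector(wv %*% dy))
  })
}

#' Spatial weighting unit
#'
#' Computes per-channel weights from the global spatial context: global
#' average pooling, a pointwise convolution, ReLU, a second pointwise
#' convolution, and a sigmoid; the input is rescaled channel-wise, so each
#' output element receives a contribution from every spatial position.
#'
#' @param x Array `(C, X, Y, Z)`.
#' @param w1,w2 Optional `C x C` weight matrices for the two pointwise
#'   convolutions; default zeros, yielding weights of exactly 0.5.
#' @return Array shaped like `x`.
#' @export
swu_forward <- function(x, w1 = NULL, w2 = NULL) {
  C <- dim(x)[1]
  mod <- new_swu(C, init = "zero")
  if (!is.null(w1)) mod$w1$value <- matrix(w1, C, C)
  if (!is.null(w2)) mod$w2$value <- matrix(w2, C, C)
  out <- with_no_grad(mod$forward(ag_leaf(x)))
  out$value
}

# ---- LCC block -----------------------------------------------------------

# One lightweight conditional channel weighting block for branch
# `branch_index` of a stage with `n_active` branches.
new_lcc <- function(branch_channels, branch_index, n_active,
                    ctx = new_build_ctx(), name = "lcc", init = "he") {
  C <- branch_channels[branch_index]
  if (C %% 2 != 0) stop("branch channel count must be even", call. = FALSE)
  half <- C %/% 2L
  others <- branch_channels[setdiff(seq_len(n_active), branch_index)]
  ediv <- 2L^branch_index          # branch b sits at input_extent / 2^b
  min_ediv <- 2L^n_active          # lowest-resolution branch of the stage
  cwu <- new_cwu(half, others, extent_div = ediv, min_extent_div = min_ediv,
                 ctx = ctx, name = paste0(name, ".cwu"), init = init)
  dw <- new_dwconv3d(half, extent_div = ediv, ctx = ctx,
                     name = paste0(name, ".dw"), init = init)
  swu <- new_swu(half, extent_div = ediv, ctx = ctx,
                 name = paste0(name, ".swu"), init = init)
  mod <- list(kind = "lcc", cwu = cwu, dw = dw, swu = swu, channels = C,
              branch_index = branch_index, n_active = n_active,
              concat_channels = half + sum(others))
  mod$forward <- function(branch_maps) {
    x <- branch_maps[[branch_index]]
    halves <- channel_split(x)
    other_maps <- branch_maps[setdiff(seq_len(n_active), branch_index)]
    m <- cwu$forward(halves$main, other_maps)
    m <- dw$forward(m)
    m <- swu$forward(m)
    merged <- op_concat_channels(list(m, halves$identity))
    channel_shuffle(merged, 2L)
  }
  mod
}

#' Lightweight conditional channel weighting block
#'
#' Applies one LCC block to branch `branch_index` of a stage: channel split;
#' cross-resolution channel weighting, depthwise 3x3x3 convolution and
#' spatial weighting on the main half; concatenation with the untouched
#' identity half; channel shuffle with two groups. Output shape equals the
#' branch's input shape.
#'
#' @param branch_maps List of arrays, one per active branch of the stage,
#'   ordered from highest to lowest resolution.
#' @param branch_index Which branch this block transforms.
#' @param block Optional block built with `new_lcc()`; by default a fresh
#'   randomly-initialised block matching the maps is created.
#' @return Array shaped like `branch_maps[[branch_index]]`.
#' @export
lcc_forward <- function(branch_maps, branch_index, block = NULL) {
  chans <- vapply(branch_maps, function(m) dim(m)[1], integer(1))
  if (is.null(block)) block <- new_lcc(chans, branch_index, length(branch_maps))
  out <- with_no_grad(block$forward(lapply(branch_maps, ag_leaf)))
  out$value
}

# ---- LMRF fusion operators -----------------------------------------------

# Stride-2 depthwise separable downsampling; each hop halves the extent and
# doubles the channels (depthwise 3x3x3 stride 2, then pointwise doubling).
new_down_chain <- function(cin, hops, extent_div_in, ctx = new_build_ctx(),
                           name = "down", init = "he") {
  mods <- list()
  c <- cin
  ediv <- extent_div_in
  for (h in seq_len(hops)) {
    ediv <- ediv * 2L
    mods[[h]] <- list(
      dw = new_dwconv3d(c, stride = 2L, extent_div = ediv, ctx = ctx,
                        name = paste0(name, ".hop", h, ".dw"), init = init),
      pw = new_conv3d(c, 2L * c, k = 1L, extent_div = ediv, ctx = ctx,
                      name = paste0(name, ".hop", h, ".pw"), init = init))
    c <- 2L * c
  }
  mod <- list(kind = "down_chain", hops = hops, cin = cin, cout = c, mods = mods)
  mod$forward <- function(x) {
    for (h in seq_len(hops)) {
      x <- mods[[h]]$dw$forward(x)
      x <- mods[[h]]$pw$forward(x)
    }
    x
  }
  mod
}

#' Downsample a branch map by stride-2 depthwise separable convolutions
#'
#' Each hop applies a depthwise 3x3x3 convolution with stride 2 followed by
#' a pointwise channel-doubling convolution, halving every spatial extent
#' and doubling the channel count.
#'
#' @param x Array `(C, X, Y, Z)` with extents divisible by `2^hops`.
#' @param hops Number of downsampling hops (>= 1).
#' @param chain Optional chain from `new_down_chain()`; default fresh random
#'   initialisation.
#' @return Array `(C * 2^hops, X/2^hops, ...)`.
#' @export
lmrf_downsample <- function(x, hops = 1L, chain = NULL) {
  if (hops < 1) stop("`hops` must be >= 1", call. = FALSE)
  ext <- dim(x)[-1]
  if (any(ext %% 2L^hops != 0))
    stop("spatial extent not divisible by 2^hops", call. = FALSE)
  if (is.null(chain)) chain <- new_down_chain(dim(x)[1], hops, 1L)
  out <- with_no_grad(chain$forward(ag_leaf(x)))
  out$value
}

# Ghost-style channel reduction after nearest upsampling: a pointwise
# convolution makes half the output channels, a cheap depthwise 3x3x3
# convolution on those makes the other half.
new_ghost <- function(cin, cout, extent_div = 1L, ctx = new_build_ctx(),
                      name = "ghost", init = "he") {
  if (cout %% 2 != 0) stop("ghost reduction needs an even output channel count",
                           call. = FALSE)
  pw <- new_conv3d(cin, cout %/% 2L, k = 1L, extent_div = extent_div, ctx = ctx,
                   name = paste0(name, ".pw"), init = init)
  dw <- new_dwconv3d(cout %/% 2L, extent_div = extent_div, ctx = ctx,
                     name = paste0(name, ".dw"), init = init)
  mod <- list(kind = "ghost", pw = pw, dw = dw, cin = cin, cout = cout)
  mod$forward <- function(x) {
    primary <- pw$forward(x)
    cheap <- dw$forward(primary)
    op_concat_channels(list(primary, cheap))
  }
  mod
}

#' Ghost-style channel reduction
#'
#' Produces `c_out` channels from a (typically upsampled) map: a pointwise
#' 1x1x1 convolution generates the first `c_out/2` channels and a
#' channel-preserving depthwise 3x3x3 convolution on them generates the
#' cheap second half; the two are concatenated.
#'
#' @param x Array `(C, X, Y, Z)`.
#' @param c_out Even output channel count.
#' @param module Optional module from `new_ghost()`.
#' @return Array `(c_out, X, Y, Z)`.
#' @export
ghost_reduce <- function(x, c_out, module = NULL) {
  if (is.null(module)) module <- new_ghost(dim(x)[1], c_out)
  out <- with_no_grad(module$forward(ag_leaf(x)))
  out$value
}

# Full fusion layer for a stage: every surviving branch receives the sum of
# its own map, downsampled higher-resolution maps and ghost-reduced
# upsampled lower-resolution maps; optionally a new lowest branch is
# created from the previous lowest by one downsampling hop.
new_lmrf <- function(branch_channels, n_active, add_branch = n_active < length(branch_channels),
                     ctx = new_build_ctx(), name = "lmrf", init = "he") {
  paths <- list()
  for (t in seq_len(n_active)) {
    for (j in seq_len(n_active)) {
      if (j == t) next
      key <- paste0(j, ">", t)
      if (j < t) {
        paths[[key]] <- new_down_chain(branch_channels[j], t - j, 2L^j, ctx = ctx,
                                       name = paste0(name, ".", key), init = init)
      } else {
        paths[[key]] <- new_ghost(branch_channels[j], branch_channels[t],
                                  extent_div = 2L^t, ctx = ctx,
                                  name = paste0(name, ".", key), init = init)
      }
    }
  }
  newb <- NULL
  if (add_branch) {
    newb <- new_down_chain(branch_channels[n_active], 1L, 2L^n_active, ctx = ctx,
                           name = paste0(name, ".new", n_active + 1L), init = init)
  }
  mod <- list(kind = "lmrf", paths = paths, new_branch = newb,
              n_active = n_active, channels = branch_channels)
  mod$forward <- function(branch_maps) {
    out <- vector("list", n_active + as.integer(add_branch))
    for (t in seq_len(n_active)) {
      contribs <- list(branch_maps[[t]])
      for (j in seq_len(n_active)) {
        if (j == t) next
        p <- paths[[paste0(j, ">", t)]]
        m <- branch_maps[[j]]
        if (j > t) m <- op_upsample_nearest(m, 2L^(j - t))
        contribs[[length(contribs) + 1L]] <- p$forward(m)
      }
      out[[t]] <- if (length(contribs) > 1L) op_add(contribs) else contribs[[1]]
    }
    if (add_branch) out[[n_active + 1L]] <- newb$forward(branch_maps[[n_active]])
    out
  }
  mod
}

#' Lightweight multi-resolution fusion
#'
#' Exchanges information between the parallel resolution branches of a
#' stage: each branch receives the element-wise sum of its own map,
#' stride-2 depthwise-separable downsamples of all higher-resolution
#' branches, and nearest-upsampled ghost-reduced maps of all
#' lower-resolution branches. When the stage introduces a new branch its
#' initial map is the downsample of the previous lowest branch.
#'
#' @param branch_maps List of arrays, highest to lowest resolution,
#'   following the doubling channel plan.
#' @param fusion Optional module from `new_lmrf()`; default fresh random
#'   initialisation with no new branch added.
#' @return List of fused branch maps (one longer if a branch was added).
#' @export
lmrf_fuse <- function(branch_maps, fusion = NULL) {
  chans <- vapply(branch_maps, function(m) dim(m)[1], integer(1))
  if (length(chans) > 1 && any(chans[-1] != 2L * chans[-length(chans)]))
    stop("branch maps violate the doubling channel plan", call. = FALSE)
  if (is.null(fusion)) fusion <- new_lmrf(chans, length(chans), add_branch = FALSE)
  out <- with_no_grad(fusion$forward(lapply(branch_maps, ag_leaf)))
  lapply(out, function(n) n$value)
}
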