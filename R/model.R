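# Assembly of the hierarchical multi-scale segmentation network: stem, four
# parallel-resolution stages of LCC blocks + LMRF fusion, skip connection
# and fusion head.

#' Model configuration
#'
#' Describes the network: input channels and patch extent, the doubling
#' branch channel plan, how many LCC blocks each branch runs per stage, and
#' how the three output channels are interpreted.
#'
#' @param in_channels Number of input modalities (4: FLAIR, T1, T1c, T2).
#' @param input_size Cubic input extent in voxels; must be divisible by 16.
#' @param branch_channels Channel plan of the four resolution branches;
#'   each entry must double the previous one.
#' @param lcc_blocks_per_stage LCC blocks per branch in every stage.
#' @param out_channels Output channels (3 regions).
#' @param head_mode `"region"`: sigmoid scores for the nested regions
#'   WT/TC/ET; `"label"`: softmax over background and labels 1/2/4.
#' @param groups_norm Group count for group normalization in the stem/head
#'   convolution blocks.
#' @return A validated `hmnet_config` list.
#' @export
hmnet_config <- function(in_channels = 4L, input_size = 128L,
                         branch_channels = c(32L, 64L, 128L, 256L),
                         lcc_blocks_per_stage = 1L, out_channels = 3L,
                         head_mode = c("region", "label"),
                         groups_norm = 8L) {
  head_mode <- match.arg(head_mode)
  if (length(branch_channels) != 4L)
    stop("`branch_channels` must list four branches", call. = FALSE)
  if (any(branch_channels[-1] != 2L * branch_channels[-4]))
    stop("each branch must have twice the channels of the previous branch",
         call. = FALSE)
  if (any(branch_channels %% 2L != 0L))
    stop("branch channel counts must be even", call. = FALSE)
  if (input_size %% 16L != 0L)
    stop("`input_size` must be divisible by 16", call. = FALSE)
  if (lcc_blocks_per_stage < 1L)
    stop("`lcc_blocks_per_stage` must be >= 1", call. = FALSE)
  structure(list(
    in_channels = as.integer(in_channels),
    input_size = as.integer(input_size),
    stem_channels = as.integer(branch_channels[1]),
    branch_channels = as.integer(branch_channels),
    lcc_blocks_per_stage = as.integer(lcc_blocks_per_stage),
    out_channels = as.integer(out_channels),
    head_mode = head_mode,
    groups_norm = as.integer(groups_norm)
  ), class = "hmnet_config")
}

#' Build the segmentation network
#'
#' Constructs the stem (full-resolution conv block, then a stride-2 conv
#' block), four stages of LCC blocks plus LMRF fusion over 1-4 parallel
#' branches, and the head: nearest-upsampling of all branches to the
#' highest branch resolution, 480-channel concatenation, a 3x3x3 conv
#' block, upsampling to the input extent, an element-wise skip sum with the
#' stem's full-resolution map, and a pointwise classifier.
#'
#' @param config A [hmnet_config()].
#' @param seed Optional integer seed for the parameter initialisation.
#' @return An `hmnet_model` with the parameter set and a per-layer registry
#'   used by [model_complexity()].
#' @export
hmnet_build <- function(config = hmnet_config(), seed = NULL) {
  stopifnot(inherits(config, "hmnet_config"))
  if (!is.null(seed)) set.seed(seed)
  ctx <- new_build_ctx()
  bc <- config$branch_channels
  gn <- config$groups_norm
  stem1 <- new_conv3d(config$in_channels, config$stem_channels, stride = 1L,
                      norm = TRUE, act = TRUE, groups_norm = gn,
                      extent_div = 1L, ctx = ctx, name = "stem.conv1")
  stem2 <- new_conv3d(config$stem_channels, bc[1], stride = 2L,
                      norm = TRUE, act = TRUE, groups_norm = gn,
                      extent_div = 2L, ctx = ctx, name = "stem.conv2")
  stages <- vector("list", 4L)
  for (s in 1:4) {
    n_active <- min(s, 4L)
    blocks <- list()
    for (r in seq_len(config$lcc_blocks_per_stage)) {
      blocks[[r]] <- lapply(seq_len(n_active), function(b) {
        new_lcc(bc, b, n_active, ctx = ctx,
                name = sprintf("stage%d.block%d.branch%d.lcc", s, r, b))
      })
    }
    fusion <- new_lmrf(bc, n_active, add_branch = n_active < 4L, ctx = ctx,
                       name = sprintf("stage%d.lmrf", s))
    stages[[s]] <- list(blocks = blocks, fusion = fusion, n_active = n_active)
  }
  concat_channels <- sum(bc)
  head_conv <- new_conv3d(concat_channels, bc[1], stride = 1L,
                          norm = TRUE, act = TRUE, groups_norm = gn,
                          extent_div = 2L, ctx = ctx, name = "head.conv")
  classifier <- new_conv3d(bc[1], config$out_channels, k = 1L, bias = TRUE,
                           extent_div = 1L, ctx = ctx, name = "head.classifier")
  stage2_concat <- if (length(stages) >= 2L)
    stages[[2]]$blocks[[1]][[1]]$concat_channels else NA_integer_
  # structural checks of the printed channel plan
  if (!is.na(stage2_concat) && stage2_concat != bc[1] %/% 2L + bc[2])
    stop("stage-2 LCC concatenation violates the channel plan", call. = FALSE)
  if (concat_channels != sum(bc))
    stop("head concatenation violates the channel plan", call. = FALSE)
  model <- structure(list(
    config = config,
    stem1 = stem1, stem2 = stem2, stages = stages,
    head_conv = head_conv, classifier = classifier,
    params = ctx$params,
    layers = dplyr::bind_rows(ctx$layers),
    concat_channels = concat_channels,
    stage2_concat_channels = stage2_concat
  ), class = "hmnet_model")
  model
}

#' @export
print.hmnet_model <- function(x, ...) {
  cfg <- x$config
  cat("<hmnet_model>\n")
  cat("  input:", cfg$in_channels, "x", cfg$input_size, "^3\n")
  cat("  branches:", paste(cfg$branch_channels, collapse = "/"),
      "channels at extent /", paste(2L^(1:4), collapse = ", /"), "\n")
  cat("  parameters:", format(sum(vapply(x$params, function(p) length(p$value),
                                         numeric(1))), big.mark = ","), "\n")
  invisible(x)
}

# Internal forward over graph nodes; `x_node` is a (C, X, Y, Z) node.
hmnet_forward_node <- function(model, x_node, collect_stages = FALSE) {
  full <- model$stem1$forward(x_node)
  x <- model$stem2$forward(full)
  maps <- list(x)
  stage_dims <- list()
  for (s in 1:4) {
    st <- model$stages[[s]]
    for (blocks in st$blocks) {
      maps <- lapply(seq_len(st$n_active), function(b) blocks[[b]]$forward(maps))
    }
    maps <- st$fusion$forward(maps)
    if (collect_stages)
      stage_dims[[s]] <- lapply(maps, function(m) dim(m$value))
  }
  up <- lapply(seq_along(maps), function(b) op_upsample_nearest(maps[[b]], 2L^(b - 1L)))
  cat_map <- op_concat_channels(up)
  h <- model$head_conv$forward(cat_map)
  h <- op_upsample_nearest(h, 2L)
  h <- op_add(h, full)
  out <- model$classifier$forward(h)
  if (collect_stages) attr(out, "stage_dims") <- stage_dims
  out
}

#' Run the network on a multi-modal volume
#'
#' @param model An [hmnet_build()] model.
#' @param x Array `(in_channels, X, Y, Z)` with every spatial extent
#'   divisible by 16.
#' @param collect_stages Also return the per-stage branch dimensions
#'   (attribute `"stage_dims"`), for inspecting the resolution/channel plan.
#' @return An `hmnet_output`: array `(out_channels, X, Y, Z)` of raw scores
#'   with the head mode attached.
#' @export
hmnet_forward <- function(model, x, collect_stages = FALSE) {
  stopifnot(inherits(model, "hmnet_model"))
  d <- dim(x)
  if (length(d) != 4L || d[1] != model$config$in_channels)
    stop("input must be a (", model$config$in_channels, ", X, Y, Z) array",
         call. = FALSE)
  if (any(d[-1] %% 16L != 0L))
    stop("input spatial extents must be divisible by 16", call. = FALSE)
  out <- with_no_grad(hmnet_forward_node(model, ag_leaf(x),
                                         collect_stages = collect_stages))
  res <- structure(out$value, class = "hmnet_output",
                   head_mode = model$config$head_mode)
  if (collect_stages) attr(res, "stage_dims") <- attr(out, "stage_dims")
  res
}

#' Convert network scores to a label volume
#'
#' For the region head the three channels are scores for the nested regions
#' whole tumor (WT), tumor core (TC) and enhancing tumor (ET); they are
#' thresholded and composed hierarchically (ET inside TC inside WT) into
#' labels 0/2/1/4. For the label head the channels are class scores for
#' labels 1/2/4 against a background threshold.
#'
#' @param output An `hmnet_output` (or a `(3, X, Y, Z)` array).
#' @param threshold Score threshold on the sigmoid scale.
#' @return Integer array `(X, Y, Z)` with values in \{0, 1, 2, 4\}.
#' @export
predict_labels <- function(output, threshold = 0.5) {
  head_mode <- attr(output, "head_mode") %||% "region"
  scores <- unclass(output)
  p <- 1 / (1 + exp(-scores))
  d <- dim(p)[-1]
  if (head_mode == "region") {
    wt <- p[1, , , ] > threshold
    tc <- (p[2, , , ] > threshold) & wt
    et <- (p[3, , , ] > threshold) & tc
    lab <- array(0L, dim = d)
    lab[wt] <- 2L
    lab[tc] <- 1L
    lab[et] <- 4L
  } else {
    bg <- apply(p, 2:4, max) <= threshold
    cls <- apply(p, 2:4, which.max)
    lab <- array(c(1L, 2L, 4L)[cls], dim = d)
    lab[bg] <- 0L
  }
  lab
}
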