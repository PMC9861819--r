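# Training loop (Adam, region Dice + BCE loss), cross-validation split,
# whole-case inference and checkpointing.

#' Training configuration
#'
#' Defaults follow the benchmark protocol: Adam with an initial learning
#' rate of 1e-4, batch size 2, up to 500 epochs, five folds. Desk-scale
#' runs bound the work with `max_steps`.
#'
#' @param lr Initial Adam learning rate.
#' @param batch_size Cases per optimisation step (accumulated gradients).
#' @param max_epochs Maximum passes over the training cases.
#' @param max_steps Hard cap on optimisation steps (`Inf` to disable).
#' @param folds Cross-validation folds.
#' @param seed Seed for shuffling, augmentation and cropping.
#' @param patch_size Training patch extent per axis.
#' @param augment Apply random flips/rotation.
#' @param crop_mode `"random"` (tumor-biased) or `"center"`.
#' @param normalize Z-score each case before cropping.
#' @param eval_every Evaluate training-set region Dice every this many
#'   steps (0 = never).
#' @param patience Early-stop patience on the smoothed loss (`Inf` to
#'   disable).
#' @param stop_dice_wt Stop as soon as an evaluation reaches this
#'   whole-tumor Dice (`NULL` to disable); only meaningful with
#'   `eval_every > 0`.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 2L, max_epochs = 500L,
                         max_steps = Inf, folds = 5L, seed = 0L,
                         patch_size = 128L, augment = TRUE,
                         crop_mode = c("random", "center"), normalize = TRUE,
                         eval_every = 0L, patience = Inf,
                         stop_dice_wt = NULL) {
  crop_mode <- match.arg(crop_mode)
  stopifnot(folds >= 2L, batch_size >= 1L, lr >= 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = max_epochs, max_steps = max_steps,
                 folds = as.integer(folds), seed = as.integer(seed),
                 patch_size = as.integer(patch_size), augment = augment,
                 crop_mode = crop_mode, normalize = normalize,
                 eval_every = as.integer(eval_every), patience = patience,
                 stop_dice_wt = stop_dice_wt),
            class = "train_config")
}

#' Deterministic k-fold split of a case index
#'
#' Shuffles the case ids with the given seed and partitions them into
#' near-equal parts; earlier parts absorb the remainder. Fold `i` uses part
#' `i` for validation and the rest for training.
#'
#' @param index A [discover_cases()] tibble (or a character vector of ids).
#' @param folds Number of folds.
#' @param seed Shuffle seed.
#' @return A tibble with columns `fold`, `train` and `val` (list-columns of
#'   case ids).
#' @export
kfold_split <- function(index, folds = 5L, seed = 0L) {
  ids <- if (is.data.frame(index)) index$case_id else as.character(index)
  if (length(ids) < folds)
    stop("need at least `folds` cases (", folds, "), got ", length(ids),
         call. = FALSE)
  set.seed(seed)
  ids <- sample(ids)
  sizes <- rep(length(ids) %/% folds, folds)
  extra <- length(ids) %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  purrr::map_dfr(seq_len(folds), function(i) {
    val <- sort(ids[starts[i]:stops[i]])
    tibble::tibble(fold = i, train = list(sort(setdiff(ids, val))),
                   val = list(val))
  })
}

# Region targets (WT/TC/ET channels) from a label patch.
region_target <- function(label) {
  m <- region_masks(label)
  tgt <- array(0, dim = c(3L, dim(label)))
  tgt[1, , , ] <- m$WT
  tgt[2, , , ] <- m$TC
  tgt[3, , , ] <- m$ET
  tgt
}

new_adam <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, params) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    p$value <- p$value - st$lr * (st$m[[i]] / bc1) /
      (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(st)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

load_samples <- function(data) {
  if (is.data.frame(data)) {
    lapply(seq_len(nrow(data)), function(i) read_case(data[i, ]))
  } else if (inherits(data, "brats_case")) {
    list(data)
  } else {
    stopifnot(is.list(data), all(vapply(data, inherits, logical(1), "brats_case")))
    data
  }
}

#' Train a model
#'
#' Iterates augmented, cropped patches with Adam on the mean over the three
#' region channels of soft Dice loss plus binary cross-entropy. Aborts with
#' diagnostics if the loss becomes non-finite. Fully reproducible given
#' `cfg$seed`.
#'
#' @param model An [hmnet_build()] model (updated in place and returned).
#' @param data A [discover_cases()] index, a list of `brats_case` samples,
#'   or a single sample.
#' @param cfg A [train_config()].
#' @param quiet Suppress progress messages.
#' @return An `hmnet_fit`: list with the trained `model`, the per-step
#'   `log` tibble (columns `step`, `epoch`, `loss`, and `dice_wt`/`dice_tc`
#'   /`dice_et` at evaluation steps) and the config.
#' @export
hmnet_train <- function(model, data, cfg = train_config(), quiet = TRUE) {
  stopifnot(inherits(model, "hmnet_model"), inherits(cfg, "train_config"))
  samples <- load_samples(data)
  if (cfg$normalize)
    samples <- lapply(samples, function(s) {
      s$image <- suppressWarnings(normalize_volume(s$image))
      s
    })
  params <- model$params
  opt <- new_adam(params, cfg$lr)
  set.seed(cfg$seed)
  log_rows <- list()
  step <- 0L
  best_loss <- Inf
  since_best <- 0L
  done <- FALSE
  for (epoch in seq_len(min(cfg$max_epochs, 1e6))) {
    order_idx <- sample(length(samples))
    b <- 0L
    while (b < length(order_idx)) {
      take <- order_idx[seq(b + 1L, min(b + cfg$batch_size, length(order_idx)))]
      b <- b + length(take)
      zero_grads(params)
      loss_acc <- 0
      for (si in take) {
        s <- samples[[si]]
        if (cfg$augment) s <- augment_sample(s)
        s <- crop_to_patch(s, extent = cfg$patch_size, mode = cfg$crop_mode)
        tgt <- region_target(s$label)
        out <- hmnet_forward_node(model, ag_leaf(s$image))
        loss <- op_dice_bce_loss(out, tgt)
        if (!is.finite(loss$value))
          stop("non-finite loss at step ", step + 1L,
               " (case ", s$case_id, "); aborting", call. = FALSE)
        ag_backward(loss, seed = 1 / length(take))
        loss_acc <- loss_acc + loss$value / length(take)
      }
      adam_step(opt, params)
      step <- step + 1L
      row <- tibble::tibble(step = step, epoch = epoch, loss = loss_acc,
                            dice_wt = NA_real_, dice_tc = NA_real_,
                            dice_et = NA_real_)
      if (cfg$eval_every > 0L && step %% cfg$eval_every == 0L) {
        dice <- training_dice(model, samples)
        row$dice_wt <- dice[["WT"]]; row$dice_tc <- dice[["TC"]]
        row$dice_et <- dice[["ET"]]
        if (!quiet)
          message(sprintf("step %d loss %.4f dice WT %.3f", step, loss_acc,
                          dice[["WT"]]))
        if (!is.null(cfg$stop_dice_wt) && dice[["WT"]] >= cfg$stop_dice_wt)
          done <- TRUE
      }
      log_rows[[length(log_rows) + 1L]] <- row
      if (loss_acc < best_loss - 1e-5) {
        best_loss <- loss_acc
        since_best <- 0L
      } else since_best <- since_best + 1L
      if (done || step >= cfg$max_steps || since_best > cfg$patience) {
        done <- TRUE
        break
      }
    }
    if (done) break
  }
  structure(list(model = model, log = dplyr::bind_rows(log_rows), config = cfg),
            class = "hmnet_fit")
}

# Mean region Dice of whole-sample predictions over the training samples.
training_dice <- function(model, samples) {
  res <- vapply(samples, function(s) {
    pred <- predict_case(model, s, normalize = FALSE)
    pm <- region_masks(pred)
    tm <- region_masks(s$label)
    c(WT = dice_coefficient(pm$WT, tm$WT),
      TC = dice_coefficient(pm$TC, tm$TC),
      ET = dice_coefficient(pm$ET, tm$ET))
  }, numeric(3))
  rowMeans(res)
}

#' Predict the label volume of one case
#'
#' Standardizes, pads/crops to the model patch extent (center crop), runs
#' the network, converts scores to labels and pastes the patch back onto
#' the native grid. With `sliding = TRUE` the volume is instead covered by
#' overlapping patch windows whose scores are averaged.
#'
#' @param model An [hmnet_build()] model.
#' @param sample A `brats_case`.
#' @param sliding Use sliding-window inference over the padded volume.
#' @param normalize Standardize the case first.
#' @return Integer label array of the case's native extent.
#' @export
predict_case <- function(model, sample, sliding = FALSE, normalize = TRUE) {
  if (normalize)
    sample$image <- suppressWarnings(normalize_volume(sample$image))
  extent <- min(model$config$input_size,
                as.integer(ceiling(max(dim(sample$image)[-1]) / 16) * 16))
  s <- crop_to_patch(sample, extent = extent, mode = "center")
  if (!sliding || all(s$crop$extent >= s$crop$padded)) {
    out <- hmnet_forward(model, s$image)
    return(paste_back(predict_labels(out), s$crop))
  }
  # sliding window over the padded grid, averaging overlapping scores
  img <- sample$image
  native <- dim(img)[-1]
  padded <- as.integer(ceiling(pmax(native, extent) / 16) * 16)
  full <- array(0, dim = c(4L, padded))
  full[, seq_len(native[1]), seq_len(native[2]), seq_len(native[3])] <- img
  scores <- array(0, dim = c(model$config$out_channels, padded))
  counts <- array(0, dim = padded)
  starts <- lapply(1:3, function(a) {
    if (padded[a] <= extent) return(1L)
    unique(as.integer(round(seq(1L, padded[a] - extent + 1L,
                                length.out = ceiling(padded[a] / (extent / 2))))))
  })
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- list(sx + seq_len(min(extent, padded[1])) - 1L,
               sy + seq_len(min(extent, padded[2])) - 1L,
               sz + seq_len(min(extent, padded[3])) - 1L)
    out <- hmnet_forward(model, full[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
    scores[, ix[[1]], ix[[2]], ix[[3]]] <-
      scores[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE] + unclass(out)
    counts[ix[[1]], ix[[2]], ix[[3]]] <- counts[ix[[1]], ix[[2]], ix[[3]]] + 1
  }
  counts[counts == 0] <- 1
  scores <- sweep(scores, 2:4, counts, "/")
  lab <- predict_labels(structure(scores, head_mode = model$config$head_mode))
  lab[seq_len(native[1]), seq_len(native[2]), seq_len(native[3]), drop = FALSE]
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the model configuration and all
#' parameter values; loading rebuilds the model and restores them, so
#' save -> load -> predict is bit-identical.
#'
#' @param model An `hmnet_model` (or `hmnet_fit`).
#' @param path Checkpoint file path.
#' @return `path` / the restored `hmnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "hmnet_fit")) model <- model$model
  stopifnot(inherits(model, "hmnet_model"))
  values <- lapply(model$params, function(p) p$value)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(config = unclass(model$config), params = values), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(hmnet_config, ck$config[setdiff(names(ck$config), "stem_channels")])
  model <- hmnet_build(cfg)
  stopifnot(identical(sort(names(model$params)), sort(names(ck$params))))
  for (nm in names(ck$params)) model$params[[nm]]$value <- ck$params[[nm]]
  model
}

#' @export
print.hmnet_fit <- function(x, ...) {
  cat("<hmnet_fit>", nrow(x$log), "steps; final loss",
      sprintf("%.4f", tail(x$log$loss, 1)), "\n")
  invisible(x)
}

#' Per-step training log
#'
#' @param x An `hmnet_fit`.
#' @param ... Unused.
#' @return The log tibble (`step`, `epoch`, `loss`, region Dice columns at
#'   evaluation steps).
#' @export
tidy.hmnet_fit <- function(x, ...) x$log

#' One-row training summary
#'
#' @param x An `hmnet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: steps, epochs, final and best loss, last
#'   evaluated region Dice values.
#' @export
glance.hmnet_fit <- function(x, ...) {
  lg <- x$log
  last_eval <- dplyr::filter(lg, !is.na(.data$dice_wt))
  tibble::tibble(
    steps = nrow(lg),
    epochs = max(lg$epoch),
    final_loss = tail(lg$loss, 1),
    best_loss = min(lg$loss),
    dice_wt = if (nrow(last_eval)) tail(last_eval$dice_wt, 1) else NA_real_,
    dice_tc = if (nrow(last_eval)) tail(last_eval$dice_tc, 1) else NA_real_,
    dice_et = if (nrow(last_eval)) tail(last_eval$dice_et, 1) else NA_real_
  )
}
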