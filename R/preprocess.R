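# Intensity standardization, augmentation, and patch cropping with an
# invertible mapping back to the native grid.

#' Z-score standardization over the brain mask
#'
#' Standardizes each modality over its nonzero (brain) voxels; background
#' voxels stay exactly 0. A modality whose brain voxels are constant is set
#' to 0 inside the mask; an all-zero modality is returned unchanged with a
#' warning.
#'
#' @param image Array `(C, X, Y, Z)`.
#' @return Standardized array of the same shape.
#' @export
normalize_volume <- function(image) {
  stopifnot(length(dim(image)) == 4L)
  out <- image
  for (c in seq_len(dim(image)[1])) {
    v <- image[c, , , ]
    mask <- v != 0
    if (!any(mask)) {
      warning("modality ", c, " is all zero; left unchanged", call. = FALSE)
      next
    }
    mu <- mean(v[mask])
    sd_ <- sqrt(mean((v[mask] - mu)^2))  # population sd over the brain mask
    v[mask] <- if (sd_ > 0) (v[mask] - mu) / sd_ else 0
    out[c, , , ] <- v
  }
  out
}

#' Random flips and in-plane rotation augmentation
#'
#' Mirrors the volume along each of the sagittal, coronal and axial axes
#' independently with probability `p_flip`, then rotates by an angle drawn
#' uniformly from `(-rot_range, rot_range)` degrees about the axial axis
#' (linear interpolation for image channels, nearest-neighbour for the
#' label so the label set is preserved).
#'
#' @param sample A case sample: list with `image` `(C, X, Y, Z)` and
#'   optionally `label` `(X, Y, Z)`.
#' @param p_flip Per-axis flip probability.
#' @param rot_range Rotation half-range in degrees.
#' @return The augmented sample.
#' @export
augment_sample <- function(sample, p_flip = 0.5, rot_range = 10) {
  img <- sample$image
  lab <- sample$label
  for (ax in 1:3) {
    if (runif(1) < p_flip) {
      idx <- rev(seq_len(dim(img)[ax + 1L]))
      img <- switch(ax,
                    img[, idx, , , drop = FALSE],
                    img[, , idx, , drop = FALSE],
                    img[, , , idx, drop = FALSE])
      if (!is.null(lab)) {
        lab <- switch(ax,
                      lab[idx, , , drop = FALSE],
                      lab[, idx, , drop = FALSE],
                      lab[, , idx, drop = FALSE])
        dim(lab) <- dim(sample$label)
      }
    }
  }
  theta <- runif(1, -rot_range, rot_range) * pi / 180
  if (abs(theta) > 0) {
    rot <- rotation_maps(dim(img)[2], dim(img)[3], theta)
    img2 <- img
    for (c in seq_len(dim(img)[1]))
      for (z in seq_len(dim(img)[4]))
        img2[c, , , z] <- apply_rotation_linear(img[c, , , z], rot)
    img <- img2
    if (!is.null(lab)) {
      lab2 <- lab
      for (z in seq_len(dim(lab)[3]))
        lab2[, , z] <- apply_rotation_nearest(lab[, , z], rot)
      lab <- lab2
    }
  }
  sample$image <- img
  sample$label <- lab
  sample
}

# Precompute source coordinates for an in-plane rotation about the slice
# center (inverse mapping: output pixel -> input location).
rotation_maps <- function(nx, ny, theta) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  dx <- g$x - cx; dy <- g$y - cy
  sx <- cos(theta) * dx + sin(theta) * dy + cx
  sy <- -sin(theta) * dx + cos(theta) * dy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  clampi <- function(v, n) pmin(pmax(v, 1L), n)
  inside <- sx >= 1 & sx <= nx & sy >= 1 & sy <= ny
  list(nx = nx, ny = ny, inside = inside,
       x0 = clampi(x0, nx), x1 = clampi(x0 + 1, nx),
       y0 = clampi(y0, ny), y1 = clampi(y0 + 1, ny),
       fx = fx, fy = fy,
       xn = clampi(round(sx), nx), yn = clampi(round(sy), ny))
}

apply_rotation_linear <- function(slice, r) {
  v <- (1 - r$fx) * (1 - r$fy) * slice[cbind(r$x0, r$y0)] +
    r$fx * (1 - r$fy) * slice[cbind(r$x1, r$y0)] +
    (1 - r$fx) * r$fy * slice[cbind(r$x0, r$y1)] +
    r$fx * r$fy * slice[cbind(r$x1, r$y1)]
  v[!r$inside] <- 0
  matrix(v, r$nx, r$ny)
}

apply_rotation_nearest <- function(slice, r) {
  v <- slice[cbind(r$xn, r$yn)]
  v[!r$inside] <- 0L
  matrix(v, r$nx, r$ny)
}

#' Crop (or pad) a case to the network patch extent
#'
#' Pads every axis with zeros up to the patch extent where needed (the
#' native 155-slice axis pads to 160 so extents divide by 16), then crops:
#' at training time a random window biased to contain tumor voxels when a
#' label is present, at inference the centered window. The offsets and
#' native extent are recorded so predictions can be pasted back.
#'
#' @param sample Case sample (list with `image`, optional `label`).
#' @param extent Patch extent per axis.
#' @param mode `"center"` or `"random"`.
#' @return The cropped sample with a `crop` field (offsets, padded and
#'   native extents) for [paste_back()].
#' @export
crop_to_patch <- function(sample, extent = 128L, mode = c("center", "random")) {
  mode <- match.arg(mode)
  img <- sample$image
  native <- dim(img)[-1]
  padded <- pmax(native, extent)
  padded <- as.integer(ceiling(padded / 16) * 16)
  if (any(padded != native)) {
    img2 <- array(0, dim = c(dim(img)[1], padded))
    img2[, seq_len(native[1]), seq_len(native[2]), seq_len(native[3])] <- img
    img <- img2
    if (!is.null(sample$label)) {
      lab2 <- array(0L, dim = padded)
      lab2[seq_len(native[1]), seq_len(native[2]), seq_len(native[3])] <- sample$label
      sample$label <- lab2
    }
  }
  extent <- rep(as.integer(extent), length.out = 3L)
  extent <- pmin(extent, padded)
  room <- padded - extent
  off <- as.integer(room %/% 2L)
  if (mode == "random") {
    if (!is.null(sample$label) && any(sample$label > 0)) {
      # pick a window guaranteed to contain a random tumor voxel
      idx <- which(sample$label > 0)
      v <- idx[sample.int(length(idx), 1L)]
      co <- arrayInd(v, padded)
      lo <- pmax(co - extent + 1L, 1L)
      hi <- pmin(co, padded - extent + 1L)
      hi <- pmax(hi, lo)
      off <- as.integer(lo + floor(runif(3) * (hi - lo + 1L))) - 1L
      off <- pmin(pmax(off, 0L), room)
    } else {
      off <- as.integer(floor(runif(3) * (room + 1L)))
    }
  }
  ix <- lapply(1:3, function(a) off[a] + seq_len(extent[a]))
  sample$image <- img[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  if (!is.null(sample$label))
    sample$label <- sample$label[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  sample$crop <- list(offset = off, extent = extent, padded = padded,
                      native = native)
  sample
}

#' Paste a patch prediction back onto the native grid
#'
#' Inverse of [crop_to_patch()]: places the patch at its recorded offsets
#' inside the padded grid and trims the padding back to the native extent;
#' voxels outside the patch window are background.
#'
#' @param labels Integer array of the patch extent.
#' @param crop The `crop` record from [crop_to_patch()].
#' @return Integer array of the native extent.
#' @export
paste_back <- function(labels, crop) {
  full <- array(0L, dim = crop$padded)
  ix <- lapply(1:3, function(a) crop$offset[a] + seq_len(crop$extent[a]))
  full[ix[[1]], ix[[2]], ix[[3]]] <- labels
  full[seq_len(crop$native[1]), seq_len(crop$native[2]), seq_len(crop$native[3]),
       drop = FALSE]
}
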