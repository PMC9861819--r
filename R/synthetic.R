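# Synthetic BraTS-like phantoms: an ellipsoidal brain containing three
# nested tumor ellipsoids (edema > tumor core > enhancing core), rendered
# into four modality channels with modality-dependent contrast and additive
# Gaussian noise. Sufficient to exercise IO, preprocessing, metrics and
# learning; texture realism is out of scope.

#' Phantom generator specification
#'
#' The contrast table gives the mean intensity per modality and tissue
#' class (normal brain, edema = label 2, necrotic/non-enhancing core =
#' label 1, enhancing core = label 4), on an arbitrary scanner-free scale.
#' The defaults make edema brightest on FLAIR/T2 and the enhancing core
#' brightest on T1c, mimicking the qualitative appearance of the
#' benchmark's modalities.
#'
#' @param extent Cubic volume extent in voxels.
#' @param n_cases Number of cases for [make_dataset()].
#' @param seed Base seed; case `i` is generated from `(seed, i)`.
#' @param tumor_radii Nested ellipsoid radii `(r_WT, r_TC, r_ET)` in
#'   voxels, strictly decreasing; the default scales the 64-cube radii
#'   (14, 9, 5) with the extent.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param contrast 4 x 4 matrix (modalities x classes brain/edema/necrotic/
#'   enhancing) of mean intensities.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(extent = 64L, n_cases = 1L, seed = 0L,
                         tumor_radii = round(extent * c(14, 9, 5) / 64, 1),
                         noise_sd = 0.05, contrast = default_contrast()) {
  if (length(tumor_radii) != 3L || any(diff(tumor_radii) >= 0))
    stop("`tumor_radii` must be three strictly decreasing radii", call. = FALSE)
  if (extent < 2 * tumor_radii[1])
    stop("`extent` must be at least twice the whole-tumor radius", call. = FALSE)
  stopifnot(identical(dim(contrast), c(4L, 4L)))
  structure(list(extent = as.integer(extent), n_cases = as.integer(n_cases),
                 seed = as.integer(seed), tumor_radii = as.numeric(tumor_radii),
                 noise_sd = noise_sd, contrast = contrast),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_contrast <- function() {
  m <- rbind(
    flair = c(0.40, 0.90, 0.60, 0.60),
    t1    = c(0.60, 0.40, 0.25, 0.45),
    t1ce  = c(0.55, 0.45, 0.30, 0.95),
    t2    = c(0.40, 0.80, 0.70, 0.60)
  )
  colnames(m) <- c("brain", "edema", "necrotic", "enhancing")
  m
}

ellipsoid_mask <- function(extent, center, semi) {
  ax <- seq_len(extent)
  dx2 <- outer((ax - center[1])^2 / semi[1]^2, (ax - center[2])^2 / semi[2]^2, "+")
  arr <- outer(dx2, (ax - center[3])^2 / semi[3]^2, "+")
  arr <= 1
}

#' Generate one phantom case
#'
#' Deterministic given `(spec$seed, case_seed)`: the brain ellipsoid is
#' fixed by the extent, the nested tumor ellipsoids get a random interior
#' center and mild per-axis radius jitter, each modality is a per-class
#' mean lookup plus Gaussian noise inside the brain, and the background is
#' exactly zero.
#'
#' @param spec A [phantom_spec()].
#' @param case_seed Integer distinguishing the cases of a dataset.
#' @return A `brats_case` (see [read_case()]) with 1 mm isotropic spacing.
#' @export
make_phantom <- function(spec, case_seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer((as.numeric(spec$seed) * 10007 + case_seed) %% 2147483629))
  n <- spec$extent
  ctr <- rep((n + 1) / 2, 3)
  brain_semi <- n * c(0.46, 0.42, 0.40)
  brain <- ellipsoid_mask(n, ctr, brain_semi)
  r <- spec$tumor_radii
  jit <- matrix(runif(9, 0.9, 1.1), 3, 3)
  # tumor center inside the brain with room for the whole-tumor ellipsoid
  room <- pmax(brain_semi - max(r) * 1.1 - 1, 0)
  u <- runif(3, -1, 1) * room * 0.7
  tc <- ctr + u
  wt <- ellipsoid_mask(n, tc, r[1] * jit[, 1]) & brain
  core <- ellipsoid_mask(n, tc, r[2] * jit[, 2]) & wt
  enh <- ellipsoid_mask(n, tc, r[3] * jit[, 3]) & core
  lab <- array(0L, dim = rep(n, 3))
  lab[wt] <- 2L
  lab[core] <- 1L
  lab[enh] <- 4L
  cls <- array(0L, dim = rep(n, 3))     # 0 bg, 1 brain, 2 edema, 3 necro, 4 enh
  cls[brain] <- 1L
  cls[lab == 2L] <- 2L
  cls[lab == 1L] <- 3L
  cls[lab == 4L] <- 4L
  img <- array(0, dim = c(4L, rep(n, 3)))
  nb <- sum(brain)
  for (m in 1:4) {
    ch <- array(0, dim = rep(n, 3))
    ch[brain] <- spec$contrast[m, cls[brain]] + rnorm(nb, sd = spec$noise_sd)
    img[m, , , ] <- ch
  }
  structure(list(case_id = sprintf("phantom_%03d", case_seed), image = img,
                 label = lab, spacing = c(1, 1, 1), reference = NULL,
                 geometry = list(brain_center = ctr, brain_semi = brain_semi,
                                 tumor_center = tc,
                                 tumor_semi = cbind(WT = r[1] * jit[, 1],
                                                    TC = r[2] * jit[, 2],
                                                    ET = r[3] * jit[, 3]))),
            class = "brats_case")
}

#' Write a phantom dataset in BraTS layout
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output root; one sub-directory per case.
#' @return The [discover_cases()] index of the written dataset.
#' @export
make_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(spec$n_cases)) {
    case <- make_phantom(spec, i)
    d <- file.path(out_dir, case$case_id)
    dir.create(d, showWarnings = FALSE)
    for (m in seq_along(BRATS_MODALITIES)) {
      v <- case$image[m, , , ]
      RNifti::writeNifti(RNifti::asNifti(array(v, dim = dim(v))),
                         file.path(d, paste0(case$case_id, "_",
                                             BRATS_MODALITIES[m], ".nii.gz")))
    }
    write_prediction(case$label, NULL,
                     file.path(d, paste0(case$case_id, "_seg.nii.gz")))
  }
  discover_cases(out_dir)
}
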