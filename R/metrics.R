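# Segmentation accuracy metrics: region composition, Dice overlap, and the
# (95th-percentile) Hausdorff surface distance.

#' Compose the evaluated tumor regions from a label volume
#'
#' Whole tumor (WT) is the union of labels 1, 2 and 4; tumor core (TC) is
#' labels 1 and 4; enhancing tumor (ET) is label 4. By construction
#' ET is inside TC is inside WT.
#'
#' @param labels Integer array with values in \{0, 1, 2, 4\}.
#' @param spacing Voxel spacing in mm per axis.
#' @return A `region_masks` list with logical arrays `ET`, `WT`, `TC` and
#'   the spacing.
#' @export
region_masks <- function(labels, spacing = c(1, 1, 1)) {
  vals <- unique(as.integer(labels))
  bad <- setdiff(vals, c(0L, 1L, 2L, 4L))
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    ET = labels == 4L,
    WT = labels == 1L | labels == 2L | labels == 4L,
    TC = labels == 1L | labels == 4L,
    spacing = spacing
  ), class = "region_masks")
}

#' Dice similarity coefficient
#'
#' `2*TP / (FP + 2*TP + FN)` between two binary masks; 1 when both masks
#' are empty.
#'
#' @param pred,truth Logical (or 0/1) arrays of identical shape.
#' @return Dice in \[0, 1\].
#' @export
dice_coefficient <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (fp + 2 * tp + fn)
}

# Directed surface distances from every boundary voxel of `a` to the
# nearest boundary voxel of `b` (6-connectivity boundaries, mm units).
directed_surface_dists <- function(a, b, spacing) {
  sa <- cpp_surface_voxels(as.logical(a), dim(a))
  sb <- cpp_surface_voxels(as.logical(b), dim(b))
  cpp_min_dists(sa, sb, as.numeric(spacing))
}

#' Hausdorff distance between binary masks
#'
#' The symmetric surface distance `max(sup_p inf_t d(p,t), sup_t inf_p
#' d(t,p))` over boundary voxels, in mm. `hd95()` replaces each directed
#' supremum with its 95th percentile, the standard robustified form.
#'
#' An empty prediction against a nonempty truth (or vice versa) returns the
#' benchmark penalty distance `373.13`; two empty masks give 0.
#'
#' @param pred,truth Logical arrays of identical shape.
#' @param spacing Voxel spacing in mm per axis.
#' @param percentile Percentile of the directed distances (100 = classic
#'   Hausdorff).
#' @return Distance in mm.
#' @export
hd95 <- function(pred, truth, spacing = c(1, 1, 1), percentile = 95) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  np <- sum(pred); nt <- sum(truth)
  if (np == 0 && nt == 0) return(0)
  if (np == 0 || nt == 0) return(373.13)
  d_pt <- directed_surface_dists(pred, truth, spacing)
  d_tp <- directed_surface_dists(truth, pred, spacing)
  if (percentile >= 100) return(max(max(d_pt), max(d_tp)))
  max(quantile(d_pt, percentile / 100, names = FALSE),
      quantile(d_tp, percentile / 100, names = FALSE))
}

#' @rdname hd95
#' @export
hausdorff_distance <- function(pred, truth, spacing = c(1, 1, 1)) {
  hd95(pred, truth, spacing, percentile = 100)
}

#' Evaluate predicted label volumes against ground truth
#'
#' Computes Dice and 95th-percentile Hausdorff distance for the ET/WT/TC
#' regions of every case.
#'
#' @param pred Either a directory of predicted NIfTI label volumes (named
#'   `<case_id>.nii.gz` or `<case_id>_seg.nii.gz`) or a named list of label
#'   arrays.
#' @param truth Either a BraTS-layout dataset root (truth read from each
#'   case's `seg` volume), a directory of label volumes, or a named list of
#'   label arrays.
#' @param spacing Voxel spacing in mm.
#' @return A tibble with columns `case_id`, `region`, `dice`, `hd95`.
#' @export
evaluate_predictions <- function(pred, truth, spacing = c(1, 1, 1)) {
  pred_l <- as_label_list(pred)
  truth_l <- as_label_list(truth)
  ids <- intersect(names(pred_l), names(truth_l))
  if (!length(ids)) stop("no common case ids between pred and truth", call. = FALSE)
  purrr::map_dfr(ids, function(id) {
    pm <- region_masks(pred_l[[id]], spacing)
    tm <- region_masks(truth_l[[id]], spacing)
    purrr::map_dfr(c("ET", "WT", "TC"), function(r) {
      tibble::tibble(
        case_id = id, region = r,
        dice = dice_coefficient(pm[[r]], tm[[r]]),
        hd95 = hd95(pm[[r]], tm[[r]], spacing)
      )
    })
  })
}

# Accepts a named list of arrays, a dataset root in BraTS layout, or a flat
# directory of NIfTI label files.
as_label_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    stopifnot(!is.null(names(x)))
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L, dir.exists(x))
  idx <- tryCatch(discover_cases(x, require_seg = TRUE, quiet = TRUE),
                  error = function(e) NULL)
  if (!is.null(idx) && nrow(idx) > 0) {
    labs <- lapply(idx$seg, function(f) {
      a <- RNifti::readNifti(f)
      array(as.integer(round(a)), dim = dim(a))
    })
    return(setNames(labs, idx$case_id))
  }
  files <- list.files(x, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stop("no NIfTI volumes found under ", x, call. = FALSE)
  ids <- sub("_seg$", "", sub("\\.nii(\\.gz)?$", "", basename(files)))
  labs <- lapply(files, function(f) {
    a <- RNifti::readNifti(f)
    array(as.integer(round(a)), dim = dim(a))
  })
  setNames(labs, ids)
}
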