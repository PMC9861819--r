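# Readers/writers for BraTS-layout cases:
#   <root>/<case_id>/<case_id>_<modality>.nii.gz
# with modalities flair/t1/t1ce/t2 and an optional seg label volume.
# Arrays are ordered (channels, sagittal, coronal, axial), matching the
# NIfTI voxel axis order of the benchmark volumes.

BRATS_MODALITIES <- c("flair", "t1", "t1ce", "t2")

#' Index the cases under a dataset root
#'
#' One row per case directory containing all four modality files; cases
#' with a missing modality are skipped with a warning. The segmentation is
#' optional (validation cases).
#'
#' @param root Dataset root directory.
#' @param require_seg Drop cases without a `seg` volume.
#' @param quiet Suppress the missing-modality warnings.
#' @return A tibble with columns `case_id`, `flair`, `t1`, `t1ce`, `t2`,
#'   `seg` (path or `NA`), ordered by `case_id`.
#' @export
discover_cases <- function(root, require_seg = FALSE, quiet = FALSE) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  rows <- purrr::map(dirs, function(d) {
    id <- basename(d)
    paths <- vapply(c(BRATS_MODALITIES, "seg"), function(m) {
      cands <- file.path(d, paste0(id, "_", m, c(".nii.gz", ".nii")))
      hit <- cands[file.exists(cands)]
      if (length(hit)) hit[1] else NA_character_
    }, character(1))
    if (anyNA(paths[BRATS_MODALITIES])) {
      if (!quiet)
        warning("case ", id, " skipped: missing ",
                paste(BRATS_MODALITIES[is.na(paths[BRATS_MODALITIES])],
                      collapse = ", "), call. = FALSE)
      return(NULL)
    }
    tibble::tibble(case_id = id, flair = paths[["flair"]], t1 = paths[["t1"]],
                   t1ce = paths[["t1ce"]], t2 = paths[["t2"]],
                   seg = paths[["seg"]])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(case_id = character(), flair = character(),
                          t1 = character(), t1ce = character(),
                          t2 = character(), seg = character())
  if (require_seg) out <- dplyr::filter(out, !is.na(.data$seg))
  dplyr::arrange(out, .data$case_id)
}

#' Read one case into memory
#'
#' Stacks the four modalities in the fixed channel order (FLAIR, T1, T1c,
#' T2) and attaches the label volume when present.
#'
#' @param entry One row of the [discover_cases()] index (or a list with the
#'   same fields).
#' @return A `brats_case`: list with `case_id`, `image` `(4, X, Y, Z)`,
#'   `label` (integer array or `NULL`), `spacing` (mm), and the reference
#'   NIfTI image for header-preserving writes.
#' @export
read_case <- function(entry) {
  vols <- lapply(BRATS_MODALITIES, function(m) RNifti::readNifti(entry[[m]]))
  dims <- lapply(vols, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("modalities of case ", entry$case_id, " have mismatched extents",
         call. = FALSE)
  d <- dims[[1]]
  img <- array(0, dim = c(4L, d))
  for (i in 1:4) img[i, , , ] <- vols[[i]]
  lab <- NULL
  seg <- entry[["seg"]]
  if (!is.null(seg) && length(seg) == 1L && !is.na(seg)) {
    sv <- RNifti::readNifti(seg)
    if (!identical(dim(sv), d))
      stop("label extent mismatch for case ", entry$case_id, call. = FALSE)
    lab <- array(as.integer(round(sv)), dim = d)
  }
  structure(list(case_id = entry$case_id, image = img, label = lab,
                 spacing = RNifti::pixdim(vols[[1]]),
                 reference = vols[[1]]), class = "brats_case")
}

#' Write a label volume as NIfTI
#'
#' Writes labels with the affine/header of a reference image so the
#' prediction aligns with the case geometry; reading the file back
#' reproduces the voxel values exactly.
#'
#' @param labels Integer array in \{0, 1, 2, 4\}.
#' @param reference A reference NIfTI image (e.g. the `reference` field of a
#'   [read_case()] sample), or `NULL` for a default 1 mm isotropic header.
#' @param path Output path (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_prediction <- function(labels, reference = NULL, path) {
  lab <- array(as.integer(labels), dim = dim(labels))
  img <- if (is.null(reference)) RNifti::asNifti(lab)
  else RNifti::asNifti(lab, reference = reference)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
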