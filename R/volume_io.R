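#' CT volume container
#'
#' Wraps a 3D array of Hounsfield-unit values together with the acquisition
#' metadata the downstream densitometry needs: isotropic voxel size,
#' respiratory phase and subject/timepoint identity. Gated murine thorax
#' protocols reconstruct two datasets per scan: end-inspiration (\code{P01})
#' and end-expiration (\code{P02}).
#'
#' HU values below -1000 or above +3000 are physically implausible for
#' thoracic tissue but are retained, not clamped (clamping would bias the
#' mean lung attenuation); their count is kept in the \code{n_extreme_hu}
#' field.
#'
#' @param data 3D numeric array of HU values; must be finite everywhere.
#' @param voxel_size_mm positive scalar, isotropic voxel edge in mm
#'   (default 0.05, i.e. the 50 micron reconstruction typical of murine
#'   micro-CT).
#' @param phase \code{"P01"} (end-inspiration) or \code{"P02"}
#'   (end-expiration).
#' @param subject_id character scalar.
#' @param day integer study day.
#'
#' @return An object of class \code{ct_volume}: a list with elements
#'   \code{data}, \code{voxel_size_mm}, \code{phase}, \code{subject_id},
#'   \code{day}, \code{n_extreme_hu}.
#' @export
ct_volume <- function(data, voxel_size_mm = 0.05, phase = c("P01", "P02"),
                      subject_id = "unknown", day = NA_integer_) {
  phase <- match.arg(phase)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_fibroct("fibroct_format_error", "`data` must be a 3D array of HU values")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop_fibroct("fibroct_validation_error",
                 sprintf("volume contains %d non-finite (NaN/Inf) voxel(s)", n_bad))
  if (!is_scalar_number(voxel_size_mm) || voxel_size_mm <= 0)
    stop_fibroct("fibroct_validation_error", "`voxel_size_mm` must be a positive scalar")
  structure(list(
    data = data,
    voxel_size_mm = as.numeric(voxel_size_mm),
    phase = phase,
    subject_id = as.character(subject_id),
    day = as.integer(day),
    n_extreme_hu = sum(data < -1000 | data > 3000)
  ), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s day %s phase %s | %s voxels @ %.3g mm | HU [%.0f, %.0f]\n",
              x$subject_id, x$day, x$phase,
              paste(dim(x$data), collapse = "x"),
              x$voxel_size_mm, min(x$data), max(x$data)))
  invisible(x)
}

#' Labeled lung mask
#'
#' Integer label field aligned voxel-by-voxel to a \code{\link{ct_volume}}.
#' Label scheme: 0 = background, 1 = right lung, 2 = left lung. The whole
#' lung is the union of labels 1 and 2; the two lobes are disjoint by
#' construction.
#'
#' @param labels 3D integer-valued array with values in \{0, 1, 2\}.
#' @param volume optional \code{\link{ct_volume}} to check shape against.
#'
#' @return An object of class \code{lung_mask} with elements \code{labels}
#'   and \code{label_scheme}.
#' @export
lung_mask <- function(labels, volume = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_fibroct("fibroct_format_error", "`labels` must be a 3D array")
  vals <- unique(as.vector(labels))
  bad <- setdiff(vals, c(0, 1, 2))
  if (length(bad) > 0L)
    stop_fibroct("fibroct_label_error",
                 sprintf("mask contains labels outside {0,1,2}: %s",
                         paste(sort(bad), collapse = ", ")))
  if (!is.null(volume) && !identical(dim(labels), dim(volume$data)))
    stop_fibroct("fibroct_alignment_error",
                 sprintf("mask shape (%s) does not match volume shape (%s)",
                         paste(dim(labels), collapse = "x"),
                         paste(dim(volume$data), collapse = "x")))
  storage.mode(labels) <- "integer"
  structure(list(
    labels = labels,
    label_scheme = c(background = 0L, right = 1L, left = 2L)
  ), class = "lung_mask")
}

#' Paired-phase scan for one subject at one timepoint
#'
#' Binds the end-inspiration (P01) and end-expiration (P02) volume/mask
#' pairs of one subject. The two phases are independent reconstructions and
#' may have different array shapes, but must agree on subject, day and
#' voxel size, and each volume must be shape-matched to its own mask.
#'
#' @param p01_volume,p01_mask end-inspiration \code{\link{ct_volume}} and
#'   \code{\link{lung_mask}}.
#' @param p02_volume,p02_mask end-expiration pair.
#'
#' @return An object of class \code{subject_scan_pair}.
#' @export
subject_scan_pair <- function(p01_volume, p01_mask, p02_volume, p02_mask) {
  if (p01_volume$phase != "P01" || p02_volume$phase != "P02")
    stop_fibroct("fibroct_pairing_error", "phases must be P01 and P02 respectively")
  same <- function(f) identical(p01_volume[[f]], p02_volume[[f]])
  if (!same("subject_id") || !same("day") || !same("voxel_size_mm"))
    stop_fibroct("fibroct_pairing_error",
                 "P01 and P02 must share subject_id, day and voxel_size_mm")
  for (pair in list(list(p01_volume, p01_mask), list(p02_volume, p02_mask)))
    if (!identical(dim(pair[[1]]$data), dim(pair[[2]]$labels)))
      stop_fibroct("fibroct_alignment_error", "volume and mask shapes differ within a phase")
  structure(list(
    p01 = list(volume = p01_volume, mask = p01_mask),
    p02 = list(volume = p02_volume, mask = p02_mask),
    subject_id = p01_volume$subject_id,
    day = p01_volume$day
  ), class = "subject_scan_pair")
}

#' Read a CT volume from NIfTI
#'
#' Reads a 3D NIfTI image as Hounsfield units. The voxel size is taken from
#' the file header unless overridden; anisotropic headers are rejected
#' unless \code{allow_anisotropic = TRUE}, in which case the geometric mean
#' voxel edge is used (so voxel volume is preserved).
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param phase \code{"P01"} or \code{"P02"}.
#' @param subject_id,day subject metadata.
#' @param voxel_size_mm optional override of the header spacing; a warning
#'   reports the override.
#' @param allow_anisotropic accept anisotropic voxels (default FALSE).
#'
#' @return A \code{\link{ct_volume}}.
#' @export
read_ct_volume <- function(path, phase = c("P01", "P02"), subject_id = "unknown",
                           day = NA_integer_, voxel_size_mm = NULL,
                           allow_anisotropic = FALSE) {
  phase <- match.arg(phase)
  if (!file.exists(path))
    stop_fibroct("fibroct_io_error", sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop_fibroct("fibroct_format_error",
                 sprintf("expected a 3D image, got %dD: %s", length(dim(arr)), path))
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (is.null(voxel_size_mm)) {
    if (max(spacing) - min(spacing) > 1e-6 * max(spacing)) {
      if (!allow_anisotropic)
        stop_fibroct("fibroct_format_error",
                     sprintf("anisotropic voxels (%s mm) in %s; pass allow_anisotropic = TRUE to accept",
                             paste(signif(spacing, 4), collapse = " x "), path))
      voxel_size_mm <- prod(spacing)^(1 / 3)
    } else {
      voxel_size_mm <- spacing[1]
    }
  } else {
    warning(sprintf("voxel size overridden: header %.4g mm, using %.4g mm",
                    spacing[1], voxel_size_mm))
  }
  vol <- ct_volume(arr, voxel_size_mm = voxel_size_mm, phase = phase,
                   subject_id = subject_id, day = day)
  if (vol$n_extreme_hu > 0L)
    warning(sprintf("%d voxel(s) outside the plausible HU range [-1000, 3000] retained",
                    vol$n_extreme_hu))
  vol
}

#' Read a lung mask from NIfTI
#'
#' @param path path to a NIfTI label image with values in \{0, 1, 2\}
#'   (background / right lung / left lung).
#' @param volume the \code{\link{ct_volume}} the mask belongs to; shapes
#'   must match.
#'
#' @return A \code{\link{lung_mask}}.
#' @export
read_lung_mask <- function(path, volume = NULL) {
  if (!file.exists(path))
    stop_fibroct("fibroct_io_error", sprintf("file not found: %s", path))
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L)
    stop_fibroct("fibroct_format_error", sprintf("expected a 3D mask: %s", path))
  arr <- round(arr)
  lung_mask(array(as.integer(arr), dim(arr)), volume = volume)
}

#' Write a CT volume or mask to NIfTI
#'
#' Volumes are stored as float32, masks as uint8; the isotropic voxel size
#' is written into the header.
#'
#' @param x a \code{\link{ct_volume}} or \code{\link{lung_mask}}.
#' @param path destination \code{.nii} or \code{.nii.gz} path.
#' @param voxel_size_mm voxel size to record for masks (masks carry no
#'   spacing of their own).
#' @return \code{path}, invisibly.
#' @export
write_nifti_volume <- function(x, path, voxel_size_mm = 0.05) {
  if (inherits(x, "ct_volume")) {
    arr <- x$data
    vs <- x$voxel_size_mm
    dtype <- "float"
  } else if (inherits(x, "lung_mask")) {
    arr <- x$labels
    vs <- voxel_size_mm
    dtype <- "uint8"
  } else {
    stop_fibroct("fibroct_format_error", "`x` must be a ct_volume or lung_mask")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vs, 3)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Select the voxels of a lung region
#'
#' @param mask a \code{\link{lung_mask}}.
#' @param region \code{"whole"} (labels 1 and 2), \code{"left"} (label 2)
#'   or \code{"right"} (label 1).
#'
#' @return Integer vector of linear voxel indices into the mask/volume
#'   array. Raises an empty-region error if no voxel matches (mean lung
#'   attenuation is undefined on an empty region).
#' @export
region_select <- function(mask, region = c("whole", "left", "right")) {
  region <- match.arg(region)
  wanted <- switch(region, whole = c(1L, 2L), left = 2L, right = 1L)
  idx <- which(mask$labels %in% wanted)
  if (length(idx) == 0L)
    stop_fibroct("fibroct_empty_region",
                 sprintf("region '%s' contains no voxels", region))
  idx
}

#' Read a study manifest
#'
#' The manifest is a CSV with one row per subject-day and columns
#' \code{subject_id}, \code{group}, \code{day}, \code{path_p01_vol},
#' \code{path_p01_mask}, \code{path_p02_vol}, \code{path_p02_mask}.
#' Relative paths are resolved against the manifest's own directory.
#'
#' @param path manifest CSV path.
#' @return A data.frame with the columns above (paths resolved).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_fibroct("fibroct_io_error", sprintf("manifest not found: %s", path))
  man <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("subject_id", "group", "day", "path_p01_vol", "path_p01_mask",
              "path_p02_vol", "path_p02_mask")
  missing <- setdiff(needed, names(man))
  if (length(missing) > 0L)
    stop_fibroct("fibroct_format_error",
                 sprintf("manifest lacks column(s): %s", paste(missing, collapse = ", ")))
  base <- dirname(normalizePath(path))
  for (col in grep("^path_", needed, value = TRUE)) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  man
}

#' Load one subject's paired scans from a manifest row
#'
#' @param row one row of a manifest data.frame (see
#'   \code{\link{read_manifest}}).
#' @return A \code{\link{subject_scan_pair}}.
#' @export
load_scan_pair <- function(row) {
  for (col in c("path_p01_vol", "path_p01_mask", "path_p02_vol", "path_p02_mask"))
    if (!file.exists(row[[col]]))
      stop_fibroct("fibroct_io_error",
                   sprintf("subject %s: missing file %s", row$subject_id, row[[col]]))
  v01 <- read_ct_volume(row$path_p01_vol, "P01", row$subject_id, row$day)
  m01 <- read_lung_mask(row$path_p01_mask, v01)
  v02 <- read_ct_volume(row$path_p02_vol, "P02", row$subject_id, row$day)
  m02 <- read_lung_mask(row$path_p02_mask, v02)
  subject_scan_pair(v01, m01, v02, m02)
}
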