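#' Aeration compartment HU ranges
#'
#' The preclinical Hounsfield-unit ranges that partition murine lung
#' parenchyma into aeration compartments: normo-aerated
#' \eqn{[-860, -435]} (no/mild lesions), hypo-aerated \eqn{(-435, -121)}
#' (moderate lesions) and non-aerated \eqn{[-121, 121]} (severe lesions).
#' Bracket notation is honored literally: the interval bounds -860, -435,
#' -121 and 121 belong to the closed intervals, so a voxel at exactly
#' -435 HU is normo-aerated and one at -121 HU is non-aerated. Voxels
#' outside all three ranges (hyper-aerated below -860 or dense above 121)
#' fall in a fourth \code{other} class.
#'
#' @param normo,hypo,non length-2 numeric vectors giving the interval
#'   bounds of each compartment.
#' @return An object of class \code{aeration_ranges}.
#' @export
aeration_ranges <- function(normo = c(-860, -435), hypo = c(-435, -121),
                            non = c(-121, 121)) {
  for (r in list(normo, hypo, non))
    if (length(r) != 2L || r[1] >= r[2])
      stop_fibroct("fibroct_validation_error", "each range must be an increasing length-2 vector")
  if (normo[2] > hypo[1] || hypo[2] > non[1])
    stop_fibroct("fibroct_validation_error", "compartment ranges must be ordered and disjoint")
  structure(list(normo = normo, hypo = hypo, non = non),
            class = "aeration_ranges")
}

#' Classify HU values into aeration compartments
#'
#' @param hu numeric vector of finite HU values.
#' @param ranges an \code{\link{aeration_ranges}} object.
#' @return Factor with levels \code{normo}, \code{hypo}, \code{non},
#'   \code{other}.
#' @export
classify_aeration <- function(hu, ranges = aeration_ranges()) {
  out <- rep("other", length(hu))
  out[hu >= ranges$normo[1] & hu <= ranges$normo[2]] <- "normo"
  out[hu > ranges$hypo[1] & hu < ranges$hypo[2]] <- "hypo"
  out[hu >= ranges$non[1] & hu <= ranges$non[2]] <- "non"
  factor(out, levels = c("normo", "hypo", "non", "other"))
}

#' Lung volume of a voxel set
#'
#' Volume is the voxel count times the voxel cell volume:
#' \eqn{V = N \cdot s^3} for isotropic voxel edge \eqn{s} in mm.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param voxels integer vector of linear voxel indices (from
#'   \code{\link{region_select}}).
#' @return Volume in mm^3.
#' @export
lung_volume <- function(volume, voxels) {
  if (length(voxels) == 0L)
    stop_fibroct("fibroct_empty_region", "cannot compute volume of an empty region")
  length(voxels) * volume$voxel_size_mm^3
}

#' Mean lung attenuation
#'
#' Arithmetic mean of the HU values over the selected voxels,
#' \eqn{MLA = \sum_i HU_i / N}.
#'
#' @inheritParams lung_volume
#' @return MLA in HU.
#' @export
mean_lung_attenuation <- function(volume, voxels) {
  if (length(voxels) == 0L)
    stop_fibroct("fibroct_empty_region", "MLA undefined on an empty region")
  mean(volume$data[voxels])
}

#' Air volume from lung volume and mean attenuation
#'
#' Densitometric air content \eqn{Air = V \cdot MLA / (-1000)}: a fully
#' air-filled lung (MLA = -1000 HU) contains its whole volume as air, a
#' lung at water density (MLA = 0) contains none. Applied to P01 this is
#' the inspiratory air volume; applied to P02 it is the functional residual
#' capacity (FRC). An MLA above 0 HU yields a negative value, which is
#' reported as-is with a warning rather than floored, so the volume
#' conservation identities remain exact.
#'
#' @param V lung volume in mm^3 (non-negative).
#' @param MLA mean lung attenuation in HU.
#' @return Air volume in mm^3.
#' @export
air_volume <- function(V, MLA) {
  if (V < 0)
    stop_fibroct("fibroct_validation_error", "V must be non-negative")
  air <- V * MLA / (-1000)
  if (air < 0)
    warning(sprintf("negative air volume (%.4g mm^3) from MLA = %.1f HU > 0", air, MLA))
  air
}

#' Aeration compartment fractions of a region
#'
#' Percentage of the region's voxels in each aeration compartment. The
#' denominator is all voxels of the selected region, and voxels outside
#' the three printed ranges are reported in an explicit \code{other} class,
#' so the four percentages sum to 100 but the three named compartments
#' need not.
#'
#' @inheritParams lung_volume
#' @param ranges an \code{\link{aeration_ranges}}.
#' @return Named numeric vector \code{c(normo, hypo, non, other)} in
#'   percent.
#' @export
compartment_fractions <- function(volume, voxels, ranges = aeration_ranges()) {
  if (length(voxels) == 0L)
    stop_fibroct("fibroct_empty_region", "compartment fractions undefined on an empty region")
  cls <- classify_aeration(volume$data[voxels], ranges)
  stats::setNames(100 * as.vector(table(cls)) / length(voxels), levels(cls))
}

#' HU frequency histogram of a region
#'
#' Counts over half-open bins \eqn{[left, right)} of the given width
#' spanning the region's HU range; the last bin is closed so the counts
#' sum to the region's voxel count.
#'
#' @inheritParams lung_volume
#' @param bin_width positive bin width in HU (default 10).
#' @param phase phase label recorded in the result.
#' @param region region label recorded in the result.
#' @return A data.frame with columns \code{region}, \code{phase},
#'   \code{bin_left}, \code{bin_right}, \code{count}.
#' @export
hu_histogram <- function(volume, voxels, bin_width = 10,
                         region = "whole", phase = volume$phase) {
  if (length(voxels) == 0L)
    stop_fibroct("fibroct_empty_region", "histogram undefined on an empty region")
  if (!is_scalar_number(bin_width) || bin_width <= 0)
    stop_fibroct("fibroct_validation_error", "`bin_width` must be positive")
  hu <- volume$data[voxels]
  lo <- min(hu)
  hi <- max(hu)
  nbins <- max(1L, ceiling((hi - lo) / bin_width))
  edges <- lo + bin_width * seq(0L, nbins)
  bin <- pmin(floor((hu - lo) / bin_width) + 1L, nbins)  # last bin closed
  counts <- tabulate(bin, nbins)
  data.frame(region = region, phase = phase,
             bin_left = edges[-length(edges)], bin_right = edges[-1],
             count = counts)
}

#' Full biomarker record for one subject-day and region
#'
#' Assembles every per-region micro-CT parameter and biomarker from a
#' paired-phase scan:
#' \itemize{
#'   \item per phase: voxel count \eqn{N}, volume \eqn{V = N s^3}, mean
#'     lung attenuation \eqn{MLA};
#'   \item \eqn{Air = V_{P01} MLA_{P01} / (-1000)} (inspiratory air volume)
#'     and \eqn{FRC = V_{P02} MLA_{P02} / (-1000)} (functional residual
#'     capacity);
#'   \item morphological: compartment percentages (on P02 by default) and
#'     \eqn{Tissue = V_{P02} - FRC} (non-gas lung volume, reflecting edema
#'     and collagen);
#'   \item functional: \eqn{\%Gas_{ph} = Air_{ph} \cdot 100 / V_{ph}} per
#'     phase and tidal volume \eqn{TV = Air - FRC}.
#' }
#' Note the algebraic identity \eqn{\%Gas_{ph} = -MLA_{ph}/10} implied by
#' the definitions; it is used as a self-check in the test-suite.
#'
#' @param pair a \code{\link{subject_scan_pair}}.
#' @param region \code{"whole"}, \code{"left"} or \code{"right"}.
#' @param ranges an \code{\link{aeration_ranges}}.
#' @param compartment_phase phase on which the aeration compartments are
#'   evaluated; \code{"P02"} (default) or \code{"P01"}.
#' @return A one-row data.frame (the biomarker record) with columns
#'   \code{subject_id}, \code{day}, \code{region}, \code{N_P01},
#'   \code{N_P02}, \code{V_P01}, \code{V_P02}, \code{MLA_P01},
#'   \code{MLA_P02}, \code{Air}, \code{FRC}, \code{Tissue},
#'   \code{pct_normo}, \code{pct_hypo}, \code{pct_non}, \code{pct_other},
#'   \code{pct_gas_P01}, \code{pct_gas_P02}, \code{TV}.
#' @export
functional_biomarkers <- function(pair, region = c("whole", "left", "right"),
                                  ranges = aeration_ranges(),
                                  compartment_phase = c("P02", "P01")) {
  region <- match.arg(region)
  compartment_phase <- match.arg(compartment_phase)
  if (!inherits(pair, "subject_scan_pair"))
    stop_fibroct("fibroct_pairing_error", "`pair` must be a subject_scan_pair")
  vox01 <- region_select(pair$p01$mask, region)
  vox02 <- region_select(pair$p02$mask, region)
  v01 <- pair$p01$volume
  v02 <- pair$p02$volume

  N01 <- length(vox01); N02 <- length(vox02)
  V01 <- lung_volume(v01, vox01); V02 <- lung_volume(v02, vox02)
  MLA01 <- mean_lung_attenuation(v01, vox01)
  MLA02 <- mean_lung_attenuation(v02, vox02)
  Air <- air_volume(V01, MLA01)
  FRC <- air_volume(V02, MLA02)
  comp <- if (compartment_phase == "P02") compartment_fractions(v02, vox02, ranges)
          else compartment_fractions(v01, vox01, ranges)

  data.frame(
    subject_id = pair$subject_id, day = pair$day, region = region,
    N_P01 = N01, N_P02 = N02, V_P01 = V01, V_P02 = V02,
    MLA_P01 = MLA01, MLA_P02 = MLA02,
    Air = Air, FRC = FRC, Tissue = V02 - FRC,
    pct_normo = comp[["normo"]], pct_hypo = comp[["hypo"]],
    pct_non = comp[["non"]], pct_other = comp[["other"]],
    pct_gas_P01 = Air * 100 / V01, pct_gas_P02 = FRC * 100 / V02,
    TV = Air - FRC,
    row.names = NULL
  )
}

#' Compute biomarkers for a whole study
#'
#' Runs \code{\link{functional_biomarkers}} for the whole lung and each
#' lobe over every subject-day of a manifest (or a pre-loaded list of scan
#' pairs) and returns a long biomarker table ready for
#' \code{\link{as_study_table}}.
#'
#' @param manifest a manifest data.frame (see \code{\link{read_manifest}})
#'   or a list of \code{\link{subject_scan_pair}} objects.
#' @param regions regions to evaluate (default all three).
#' @param ranges an \code{\link{aeration_ranges}}.
#' @param compartment_phase see \code{\link{functional_biomarkers}}.
#' @return A data.frame with one row per (subject, day, region), columns as
#'   in \code{\link{functional_biomarkers}} plus \code{group} when the
#'   manifest provides it.
#' @export
compute_biomarkers <- function(manifest, regions = c("whole", "left", "right"),
                               ranges = aeration_ranges(),
                               compartment_phase = "P02") {
  if (is.data.frame(manifest)) {
    pairs <- lapply(seq_len(nrow(manifest)), function(i) load_scan_pair(manifest[i, ]))
    groups <- manifest$group
  } else {
    pairs <- manifest
    groups <- vapply(pairs, function(p) attr(p, "group") %||% NA_character_, character(1))
  }
  rows <- vector("list", length(pairs) * length(regions))
  k <- 0L
  for (i in seq_along(pairs)) {
    for (rg in regions) {
      k <- k + 1L
      rec <- functional_biomarkers(pairs[[i]], rg, ranges, compartment_phase)
      rec$group <- groups[i]
      rows[[k]] <- rec
    }
  }
  do.call(rbind, rows)
}
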