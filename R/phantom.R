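#' Specification of a synthetic paired-phase thorax phantom
#'
#' Defines everything needed to generate one subject's paired
#' end-inspiration/end-expiration volumes with exact per-voxel ground
#' truth. The phantom emulates the geometry and densitometry of a murine
#' thorax: two ellipsoidal lobes with the left lobe covering about one
#' third of the total lung volume, per-compartment HU values drawn from
#' Gaussians truncated to that compartment's own HU range (so the true
#' compartment fractions are exact by construction), fibrotic lesions
#' placed with an apical and left-lobe bias, and an inspiration phase
#' derived from expiration by lobe dilation plus an aerated-voxel HU shift
#' (guaranteeing a positive tidal volume).
#'
#' @param shape integer length-3 array extents (default \code{c(64,64,64)}).
#' @param voxel_size_mm isotropic voxel edge in mm (default 0.05).
#' @param left_fraction target left/whole lung volume ratio in (0,1)
#'   (default 1/3, the murine left lobe share).
#' @param compartment_targets named fractions \code{c(normo, hypo, non)}
#'   with sum at most 1; any remainder becomes hyper-aerated \code{other}
#'   voxels.
#' @param hu_means,hu_sds named per-compartment Gaussian parameters
#'   (\code{normo}, \code{hypo}, \code{non}, \code{other}); each mean must
#'   lie inside its compartment's HU range.
#' @param lesion_apical_bias,lesion_left_bias non-negative strengths of
#'   the apical (high-z) and left-lobe preference of lesion placement. The
#'   left bias acts on the log of the per-lobe lesion quota, so
#'   \code{lesion_left_bias = b} multiplies the left lobe's per-voxel
#'   lesion burden by about \code{exp(b)} relative to the right lobe.
#' @param lobe_noise_sd standard deviation of the symmetric log-normal
#'   per-lobe lesion-burden effect (default 0.25); this is the
#'   animal-to-animal variability of the lateral lesion distribution and
#'   what makes paired left/right comparisons a proper random variable.
#' @param n_blobs number of Gaussian lesion nuclei seeding the spatially
#'   correlated lesion field.
#' @param inspiration_air_gain HU shift subtracted from aerated voxels in
#'   P01 (default 150).
#' @param inspiration_volume_gain fractional lung volume increase of P01
#'   over P02 (default 0.3).
#' @param volume_scale multiplicative scale on lobe radii cubed, i.e. on
#'   total lung volume (used for inflammation-driven volume trajectories).
#' @param ranges the \code{\link{aeration_ranges}} the HU truncation uses.
#' @param seed integer; fully determines the phantom.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         voxel_size_mm = 0.05,
                         left_fraction = 1 / 3,
                         compartment_targets = c(normo = 0.814, hypo = 0.186, non = 0),
                         hu_means = c(normo = -647.5, hypo = -278, non = 0, other = -930),
                         hu_sds = c(normo = 50, hypo = 50, non = 50, other = 20),
                         lesion_apical_bias = 2,
                         lesion_left_bias = 0,
                         lobe_noise_sd = 0.25,
                         n_blobs = 8L,
                         inspiration_air_gain = 150,
                         inspiration_volume_gain = 0.3,
                         volume_scale = 1,
                         ranges = aeration_ranges(),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop_fibroct("fibroct_spec_error", "`shape` must be 3 extents, each at least 8")
  ct <- compartment_targets
  if (!all(c("normo", "hypo", "non") %in% names(ct)))
    stop_fibroct("fibroct_spec_error", "compartment_targets needs names normo, hypo, non")
  if (any(ct < 0) || any(ct > 1) || sum(ct) > 1 + 1e-12)
    stop_fibroct("fibroct_spec_error",
                 sprintf("infeasible compartment targets (sum = %.3f > 1 or out of [0,1])", sum(ct)))
  if (left_fraction <= 0 || left_fraction >= 1)
    stop_fibroct("fibroct_spec_error", "`left_fraction` must be in (0,1)")
  if (lesion_apical_bias < 0 || lesion_left_bias < 0 || lobe_noise_sd < 0)
    stop_fibroct("fibroct_spec_error", "lesion biases and lobe noise must be non-negative")
  lims <- list(normo = ranges$normo, hypo = ranges$hypo, non = ranges$non,
               other = c(-1000, ranges$normo[1]))
  for (cmp in names(lims)) {
    m <- hu_means[[cmp]]
    if (m < lims[[cmp]][1] || m > lims[[cmp]][2])
      stop_fibroct("fibroct_spec_error",
                   sprintf("hu mean for '%s' (%.1f) lies outside its HU range [%.0f, %.0f]",
                           cmp, m, lims[[cmp]][1], lims[[cmp]][2]))
  }
  structure(list(
    shape = shape, voxel_size_mm = voxel_size_mm, left_fraction = left_fraction,
    compartment_targets = ct[c("normo", "hypo", "non")],
    hu_means = hu_means, hu_sds = hu_sds,
    lesion_apical_bias = lesion_apical_bias, lesion_left_bias = lesion_left_bias,
    lobe_noise_sd = lobe_noise_sd, n_blobs = as.integer(n_blobs),
    inspiration_air_gain = inspiration_air_gain,
    inspiration_volume_gain = inspiration_volume_gain,
    volume_scale = volume_scale, ranges = ranges, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Gaussian truncated to [lo, hi] via inverse-CDF sampling; `open` shrinks
# the bounds by a hair so open-interval compartments never emit a boundary
# value that would classify into the neighbouring closed compartment.
rtrunc_norm <- function(n, mean, sd, lo, hi, open = FALSE) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  eps <- if (open) 1e-6 * (hi - lo) else 0
  plo <- stats::pnorm(lo + eps, mean, sd)
  phi <- stats::pnorm(hi - eps, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# voxel-center coordinate arrays for a given shape (1-based indices)
coord_grids <- function(shape) {
  list(
    x = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape),
    y = array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]), shape),
    z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
  )
}

# mask of the two ellipsoidal lobes: 1 = right, 2 = left
lobe_mask <- function(shape, left_fraction, radius_scale = 1) {
  g <- coord_grids(shape)
  # left/right lobe radii: same shape, left scaled so left/right volume
  # ratio equals left_fraction / (1 - left_fraction)
  s_left <- (left_fraction / (1 - left_fraction))^(1 / 3)
  r_right <- radius_scale * c(0.21 * shape[1], 0.32 * shape[2], 0.40 * shape[3])
  r_left <- r_right * s_left
  c_right <- c(0.30 * shape[1], 0.50 * shape[2], 0.50 * shape[3])
  c_left <- c(0.72 * shape[1], 0.50 * shape[2], 0.50 * shape[3])
  inside <- function(ctr, r)
    ((g$x - ctr[1]) / r[1])^2 + ((g$y - ctr[2]) / r[2])^2 + ((g$z - ctr[3]) / r[3])^2 <= 1
  lab <- array(0L, shape)
  lab[inside(c_right, r_right)] <- 1L
  lab[inside(c_left, r_left)] <- 2L
  lab
}

# assign compartment labels to the lung voxels of one phase; counts are
# rounded from the target fractions so realized fractions ARE the ground
# truth. Lesion mass (non, then hypo) is split between the lobes by quota
# — proportional to lobe size, modulated by the symmetric per-lobe burden
# multipliers — and a propensity field (apical gradient + lesion blobs +
# noise) ranks voxels WITHIN each lobe. Quota-based allocation keeps the
# two lobes exchangeable when the multipliers are unbiased, which is what
# makes paired left/right tests calibrated on null phantoms.
assign_compartments <- function(labels, spec, blob_centers, g, lobe_mult) {
  idx <- which(labels > 0L)
  n <- length(idx)
  lobes <- labels[idx]                    # 1 = right, 2 = left
  n_lobe <- tabulate(lobes, 2L)
  n_non <- round(spec$compartment_targets[["non"]] * n)
  n_hypo <- min(round(spec$compartment_targets[["hypo"]] * n), n - n_non)
  n_other <- min(round(max(0, 1 - sum(spec$compartment_targets)) * n),
                 n - n_non - n_hypo)

  w <- n_lobe * lobe_mult
  split_quota <- function(total, cap, weights) {
    q1 <- min(round(total * weights[1] / sum(weights)), cap[1])
    q2 <- total - q1
    if (q2 > cap[2]) { q1 <- min(q1 + (q2 - cap[2]), cap[1]); q2 <- cap[2] }
    c(q1, q2)
  }
  cap <- n_lobe
  q_non <- split_quota(n_non, cap, w); cap <- cap - q_non
  q_hypo <- split_quota(n_hypo, cap, w); cap <- cap - q_hypo
  q_other <- split_quota(n_other, cap, n_lobe)  # hyper-aeration: no lesion bias

  z_norm <- (g$z[idx] - min(g$z[idx])) / max(1L, diff(range(g$z[idx])))
  prop <- spec$lesion_apical_bias * z_norm
  if (nrow(blob_centers) > 0L) {
    sigma <- 0.18 * mean(spec$shape)
    for (b in seq_len(nrow(blob_centers))) {
      d2 <- (g$x[idx] - blob_centers[b, 1])^2 + (g$y[idx] - blob_centers[b, 2])^2 +
        (g$z[idx] - blob_centers[b, 3])^2
      prop <- prop + 2 * exp(-d2 / (2 * sigma^2))
    }
  }
  prop <- prop + stats::rnorm(n, 0, 0.3)

  comp <- rep("normo", n)
  for (l in 1:2) {
    pos <- which(lobes == l)
    if (length(pos) == 0L) next
    ord <- pos[order(prop[pos], decreasing = TRUE)]
    if (q_non[l] > 0L) comp[ord[seq_len(q_non[l])]] <- "non"
    if (q_hypo[l] > 0L) comp[ord[q_non[l] + seq_len(q_hypo[l])]] <- "hypo"
    if (q_other[l] > 0L) comp[rev(ord)[seq_len(q_other[l])]] <- "other"
  }
  list(idx = idx, comp = comp)
}

# draw HU for lung voxels given compartment assignment; background soft
# tissue sits near 0 HU inside a body ellipse, air elsewhere
sample_hu <- function(labels, assign, spec, shift_aerated = 0) {
  shape <- spec$shape
  ranges <- spec$ranges
  lims <- list(normo = ranges$normo, hypo = ranges$hypo, non = ranges$non,
               other = c(-1000, ranges$normo[1] - 1))
  open <- c(normo = FALSE, hypo = TRUE, non = FALSE, other = FALSE)
  hu <- array(0, shape)
  # body: soft-tissue ellipse around the lungs over an air background
  g <- coord_grids(shape)
  body <- ((g$x - shape[1] / 2) / (0.48 * shape[1]))^2 +
    ((g$y - shape[2] / 2) / (0.48 * shape[2]))^2 +
    ((g$z - shape[3] / 2) / (0.49 * shape[3]))^2 <= 1
  hu[!body] <- -1000
  hu[body] <- stats::rnorm(sum(body), 30, 15)
  for (cmp in c("normo", "hypo", "non", "other")) {
    sel <- assign$idx[assign$comp == cmp]
    if (length(sel) == 0L) next
    hu[sel] <- rtrunc_norm(length(sel), spec$hu_means[[cmp]], spec$hu_sds[[cmp]],
                           lims[[cmp]][1], lims[[cmp]][2], open = open[[cmp]])
  }
  if (shift_aerated != 0) {
    aer <- assign$idx[assign$comp %in% c("normo", "hypo", "other")]
    hu[aer] <- pmax(hu[aer] - shift_aerated, -1000)
  }
  hu
}

# ground-truth biomarker record per region, computed directly from the
# generated arrays and labels (plain sums, no call into the biomarker API)
truth_record <- function(hu01, lab01, comp01, hu02, lab02, comp02, spec,
                         subject_id, day) {
  vs3 <- spec$voxel_size_mm^3
  rows <- lapply(c("whole", "left", "right"), function(rg) {
    want <- switch(rg, whole = c(1L, 2L), left = 2L, right = 1L)
    i01 <- which(lab01 %in% want)
    i02 <- which(lab02 %in% want)
    N01 <- length(i01); N02 <- length(i02)
    V01 <- N01 * vs3; V02 <- N02 * vs3
    MLA01 <- sum(hu01[i01]) / N01
    MLA02 <- sum(hu02[i02]) / N02
    Air <- V01 * MLA01 / (-1000)
    FRC <- V02 * MLA02 / (-1000)
    cc <- comp02[lab02[comp02$idx] %in% want, ]
    frac <- 100 * c(sum(cc$comp == "normo"), sum(cc$comp == "hypo"),
                    sum(cc$comp == "non"), sum(cc$comp == "other")) / nrow(cc)
    data.frame(subject_id = subject_id, day = day, region = rg,
               N_P01 = N01, N_P02 = N02, V_P01 = V01, V_P02 = V02,
               MLA_P01 = MLA01, MLA_P02 = MLA02,
               Air = Air, FRC = FRC, Tissue = V02 - FRC,
               pct_normo = frac[1], pct_hypo = frac[2], pct_non = frac[3],
               pct_other = frac[4],
               pct_gas_P01 = Air * 100 / V01, pct_gas_P02 = FRC * 100 / V02,
               TV = Air - FRC, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Generate one synthetic subject (paired phases + ground truth)
#'
#' Builds the end-expiration (P02) phantom from the spec, then derives
#' end-inspiration (P01) by scaling the lobe radii (volume gain) and
#' shifting aerated-voxel HU down by the inspiration air gain. Lesion
#' nuclei are shared between the phases so the two reconstructions depict
#' the same animal. The ground-truth record is computed from the
#' generator's own labels and arrays, never re-estimated.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param subject_id,day metadata stamped on the volumes.
#' @return A list with elements \code{pair}
#'   (\code{\link{subject_scan_pair}}), \code{truth} (list: per-region
#'   ground-truth \code{biomarkers} data.frame with compartments from the
#'   P02 labels, realized \code{left_fraction}, per-phase compartment
#'   label arrays \code{comp_p01}/\code{comp_p02}) and \code{spec}.
#' @export
generate_subject <- function(spec, subject_id = "phantom", day = NA_integer_) {
  if (!inherits(spec, "phantom_spec"))
    stop_fibroct("fibroct_spec_error", "`spec` must be a phantom_spec")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  rs02 <- spec$volume_scale^(1 / 3)
  rs01 <- (spec$volume_scale * (1 + spec$inspiration_volume_gain))^(1 / 3)
  lab02 <- lobe_mask(spec$shape, spec$left_fraction, rs02)
  lab01 <- lobe_mask(spec$shape, spec$left_fraction, rs01)
  g <- coord_grids(spec$shape)

  # lesion nuclei: random lung voxels with an apical preference
  lung_idx <- which(lab02 > 0L)
  z_norm <- (g$z[lung_idx] - min(g$z[lung_idx])) / max(1L, diff(range(g$z[lung_idx])))
  w <- exp(spec$lesion_apical_bias * z_norm)
  centers_i <- sample(lung_idx, spec$n_blobs, replace = TRUE, prob = w)
  blob_centers <- cbind(g$x[centers_i], g$y[centers_i], g$z[centers_i])

  # per-lobe lesion-burden multipliers (right, left): symmetric log-normal
  # animal effect, with the left bias shifting the left lobe's log-burden;
  # shared between phases so the two reconstructions depict one animal
  lobe_mult <- exp(stats::rnorm(2, 0, spec$lobe_noise_sd) +
                     c(0, spec$lesion_left_bias))

  as02 <- assign_compartments(lab02, spec, blob_centers, g, lobe_mult)
  hu02 <- sample_hu(lab02, as02, spec, shift_aerated = 0)
  as01 <- assign_compartments(lab01, spec, blob_centers, g, lobe_mult)
  hu01 <- sample_hu(lab01, as01, spec, shift_aerated = spec$inspiration_air_gain)

  v01 <- ct_volume(hu01, spec$voxel_size_mm, "P01", subject_id, day)
  v02 <- ct_volume(hu02, spec$voxel_size_mm, "P02", subject_id, day)
  pair <- subject_scan_pair(v01, lung_mask(lab01, v01), v02, lung_mask(lab02, v02))

  comp01 <- data.frame(idx = as01$idx, comp = as01$comp)
  comp02 <- data.frame(idx = as02$idx, comp = as02$comp)
  truth <- list(
    biomarkers = truth_record(hu01, lab01, comp01, hu02, lab02, comp02,
                              spec, subject_id, day),
    left_fraction = sum(lab02 == 2L) / sum(lab02 > 0L),
    comp_p01 = comp01, comp_p02 = comp02
  )
  list(pair = pair, truth = truth, spec = spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default cohort design for a bleomycin drug study
#'
#' Group sizes and per-group/day compartment trajectories emulating a
#' saline-control (SAL), bleomycin (BLM) and bleomycin + Nintedanib
#' (BLM+NINT) study read out at days 7, 14 and 21: the SAL lung is stable
#' (about 81\% normo- and 19\% hypo-aerated, no non-aerated tissue), the
#' BLM non-aerated fraction rises steeply between days 7 and 21 while the
#' treated arm's rise is attenuated, and an early inflammatory volume
#' increase decays over time.
#'
#' @param n_sal,n_blm,n_nint group sizes (defaults 4, 7, 12).
#' @return A data.frame with columns \code{group}, \code{day}, \code{n},
#'   \code{f_normo}, \code{f_hypo}, \code{f_non}, \code{volume_scale},
#'   \code{left_bias}.
#' @export
default_cohort_design <- function(n_sal = 4L, n_blm = 7L, n_nint = 12L) {
  d <- rbind(
    data.frame(group = "SAL", day = c(7, 14, 21), n = n_sal,
               f_normo = 0.814, f_hypo = 0.186, f_non = 0,
               volume_scale = 1.00, left_bias = 0.8),
    data.frame(group = "BLM", day = c(7, 14, 21), n = n_blm,
               f_normo = c(0.738, 0.480, 0.227),
               f_hypo = c(0.247, 0.315, 0.384),
               f_non = c(0.015, 0.205, 0.389),
               volume_scale = c(1.25, 1.15, 1.05), left_bias = 1.5),
    data.frame(group = "BLM+NINT", day = c(7, 14, 21), n = n_nint,
               f_normo = c(0.577, 0.530, 0.487),
               f_hypo = c(0.361, 0.376, 0.391),
               f_non = c(0.062, 0.094, 0.122),
               volume_scale = c(1.25, 1.12, 1.02), left_bias = 1.5)
  )
  d
}

#' Generate a whole synthetic cohort
#'
#' One paired-phase phantom per subject-day. Each subject gets its own
#' random stream derived by hashing the cohort seed with the subject id,
#' so regeneration is order-independent, and a subject-level random effect
#' on the compartment targets and lung volume that persists across days
#' (each animal is its own control). When \code{out_dir} is given, the
#' NIfTI volumes/masks, a manifest CSV in the package's schema and a
#' per-subject ground-truth JSON are written there.
#'
#' @param design a design data.frame as returned by
#'   \code{\link{default_cohort_design}}.
#' @param seed cohort-level integer seed.
#' @param shape phantom array extents per subject.
#' @param subject_sd standard deviation of the log-scale subject random
#'   effect on compartment targets (default 0.15).
#' @param volume_sd standard deviation of the log-scale subject random
#'   effect on lung volume (default 0.05).
#' @param out_dir optional output directory.
#' @param ... further arguments passed to \code{\link{phantom_spec}}.
#' @return A list with \code{manifest} (data.frame; file-path columns are
#'   NA unless \code{out_dir} is given), \code{subjects} (named list of
#'   \code{generate_subject} results) and \code{design}.
#' @export
generate_cohort <- function(design = default_cohort_design(), seed = 1L,
                            shape = c(48L, 48L, 48L), subject_sd = 0.15,
                            volume_sd = 0.05, out_dir = NULL, ...) {
  need <- c("group", "day", "n", "f_normo", "f_hypo", "f_non")
  if (!all(need %in% names(design)))
    stop_fibroct("fibroct_design_error",
                 sprintf("design lacks column(s): %s",
                         paste(setdiff(need, names(design)), collapse = ", ")))
  if (nrow(design) == 0L)
    stop_fibroct("fibroct_design_error", "design has no rows")
  if (any(design$n < 1L))
    stop_fibroct("fibroct_design_error", "every design cell needs at least one subject")
  groups <- unique(design$group)
  subjects <- list()
  man_rows <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  for (gidx in seq_along(groups)) {
    grp <- groups[gidx]
    gdes <- design[design$group == grp, ]
    n_subj <- unique(gdes$n)[1]
    for (s in seq_len(n_subj)) {
      sid <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", grp), s)
      # subject-level random effects, stable across days
      sseed <- derive_seed(seed, sid)
      old <- .Random.seed_save()
      set.seed(sseed)
      targ_re <- exp(stats::rnorm(3, 0, subject_sd))
      vol_re <- exp(stats::rnorm(1, 0, volume_sd))
      .Random.seed_restore(old)
      for (di in seq_len(nrow(gdes))) {
        row <- gdes[di, ]
        f <- c(row$f_normo, row$f_hypo, row$f_non) * targ_re
        f <- f * min(1, sum(c(row$f_normo, row$f_hypo, row$f_non))) / sum(f)
        spec <- phantom_spec(
          shape = shape,
          compartment_targets = c(normo = f[1], hypo = f[2], non = f[3]),
          lesion_left_bias = row$left_bias %||% 0,
          volume_scale = (row$volume_scale %||% 1) * vol_re,
          seed = derive_seed(seed, paste0(sid, "@d", row$day)),
          ...
        )
        subj <- generate_subject(spec, subject_id = sid, day = row$day)
        key <- paste0(sid, "_d", row$day)
        subjects[[key]] <- subj
        paths <- rep(NA_character_, 4)
        if (!is.null(out_dir)) {
          paths <- file.path(out_dir, paste0(key, c("_P01_vol.nii.gz", "_P01_mask.nii.gz",
                                                    "_P02_vol.nii.gz", "_P02_mask.nii.gz")))
          write_nifti_volume(subj$pair$p01$volume, paths[1])
          write_nifti_volume(subj$pair$p01$mask, paths[2], spec$voxel_size_mm)
          write_nifti_volume(subj$pair$p02$volume, paths[3])
          write_nifti_volume(subj$pair$p02$mask, paths[4], spec$voxel_size_mm)
          jsonlite::write_json(subj$truth$biomarkers,
                               file.path(out_dir, paste0(key, "_truth.json")),
                               digits = NA)
        }
        man_rows[[key]] <- data.frame(
          subject_id = sid, group = grp, day = row$day,
          path_p01_vol = paths[1], path_p01_mask = paths[2],
          path_p02_vol = paths[3], path_p02_mask = paths[4]
        )
      }
    }
  }
  manifest <- do.call(rbind, man_rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, subjects = subjects, design = design)
}
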