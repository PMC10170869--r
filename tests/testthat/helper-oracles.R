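# Independent naive-loop oracles used to cross-check the vectorized
# implementations, plus small fixture builders. Oracles deliberately use
# explicit element-by-element loops.

naive_mla <- function(hu_values) {
  s <- 0
  for (v in hu_values) s <- s + v
  s / length(hu_values)
}

naive_classify <- function(hu) {
  # bracket convention: [-860,-435] normo, (-435,-121) hypo, [-121,121] non
  if (hu >= -860 && hu <= -435) "normo"
  else if (hu > -435 && hu < -121) "hypo"
  else if (hu >= -121 && hu <= 121) "non"
  else "other"
}

naive_fractions <- function(hu_values) {
  counts <- c(normo = 0, hypo = 0, non = 0, other = 0)
  for (v in hu_values) counts[naive_classify(v)] <- counts[naive_classify(v)] + 1
  100 * counts / length(hu_values)
}

naive_histogram <- function(hu_values, bin_width) {
  lo <- min(hu_values); hi <- max(hu_values)
  nbins <- max(1, ceiling((hi - lo) / bin_width))
  counts <- rep(0L, nbins)
  for (v in hu_values) {
    b <- floor((v - lo) / bin_width) + 1
    if (b > nbins) b <- nbins  # closed last bin
    counts[b] <- counts[b] + 1L
  }
  counts
}

# Spearman via explicit average ranks then Pearson product-moment formula
naive_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i]); eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# a ct_volume holding given HU values (padded with the first value)
toy_volume <- function(values, dims = NULL, voxel_size_mm = 0.05,
                       phase = "P01", subject_id = "toy", day = 21L) {
  if (is.null(dims)) {
    n <- length(values)
    side <- ceiling(n^(1 / 3))
    dims <- c(side, side, ceiling(n / side^2))
  }
  arr <- array(values[1], dims)
  arr[seq_along(values)] <- values
  ct_volume(arr, voxel_size_mm, phase, subject_id, day)
}

# a scan pair of constant-HU phases with the given voxel counts inside an
# all-right-lung mask
constant_pair <- function(hu_p01, n_p01, hu_p02, n_p02, voxel_size_mm = 0.05,
                          subject_id = "toy", day = 21L) {
  mkphase <- function(hu, n, phase) {
    side <- ceiling((n * 2)^(1 / 3)) + 1
    arr <- array(hu, c(side, side, side))
    lab <- array(0L, c(side, side, side))
    lab[seq_len(n)] <- 1L
    v <- ct_volume(arr, voxel_size_mm, phase, subject_id, day)
    list(v = v, m = lung_mask(lab, v))
  }
  p1 <- mkphase(hu_p01, n_p01, "P01")
  p2 <- mkphase(hu_p02, n_p02, "P02")
  subject_scan_pair(p1$v, p1$m, p2$v, p2$m)
}

# small long-format study table from vectors of per-subject values
toy_study_table <- function(values_by_group, biomarker = "pct_non",
                            region = "whole", day = 21) {
  rows <- list()
  for (grp in names(values_by_group)) {
    v <- values_by_group[[grp]]
    rows[[grp]] <- data.frame(
      subject_id = paste0(grp, "_", seq_along(v)), group = grp, day = day,
      region = region, biomarker = biomarker, value = v)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_table", "data.frame")
  out
}

# left/right paired table: one row per subject per lobe
toy_lobe_table <- function(left, right, group = "BLM", day = 21,
                           biomarker = "pct_non") {
  n <- length(left)
  out <- rbind(
    data.frame(subject_id = paste0("s", 1:n), group = group, day = day,
               region = "left", biomarker = biomarker, value = left),
    data.frame(subject_id = paste0("s", 1:n), group = group, day = day,
               region = "right", biomarker = biomarker, value = right))
  class(out) <- c("study_table", "data.frame")
  out
}

# fast null/effect phantom cohort for paired-lobe calibration studies:
# one day, n subjects, returns a study table of left/right fractions
simulate_lobe_cohort <- function(n_subjects, seed, left_bias = 0,
                                 apical_bias = 0, f = c(0.75, 0.2, 0.05),
                                 shape = c(20L, 20L, 20L), biomarker = "pct_hypo") {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    spec <- phantom_spec(
      shape = shape,
      compartment_targets = c(normo = f[1], hypo = f[2], non = f[3]),
      lesion_apical_bias = apical_bias, lesion_left_bias = left_bias,
      seed = seed * 1000L + s)
    subj <- generate_subject(spec, sprintf("s%02d", s), 21L)
    for (rg in c("left", "right")) {
      rec <- suppressWarnings(functional_biomarkers(subj$pair, rg))
      rows[[paste(s, rg)]] <- data.frame(
        subject_id = rec$subject_id, group = "BLM", day = 21, region = rg,
        biomarker = biomarker,
        value = rec[[biomarker]])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_table", "data.frame")
  out
}
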