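---
title: "Methods: densitometric quantification of murine lung fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: densitometric quantification of murine lung fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroct)
```

# The measurement model

Respiratory-gated micro-CT of a free-breathing mouse yields two 3D
reconstructions per scan: end-inspiration (P01) and end-expiration (P02),
typically at 50 µm isotropic voxels. Given a Hounsfield-unit (HU) volume
and a mask labeling background (0), right lung (1) and left lung (2),
`fibroct` treats the mask as authoritative — segmentation, vessel
exclusion and gating are upstream concerns — and computes, per region
(whole / left / right) and phase:

* voxel count $N$, volume $V = N s^3$ for voxel edge $s$,
* mean lung attenuation $\mathrm{MLA} = \sum_i \mathrm{HU}_i / N$,
* densitometric air content $V \cdot \mathrm{MLA} / (-1000)$, which is
  the inspiratory air volume (Air) on P01 and the functional residual
  capacity (FRC) on P02.

Derived biomarkers: $\mathrm{Tissue} = V_{P02} - \mathrm{FRC}$ (non-gas
lung volume, tracking edema and collagen deposition),
$\mathrm{TV} = \mathrm{Air} - \mathrm{FRC}$ (tidal volume), and
$\%\mathrm{Gas}_{ph} = \mathrm{Air}_{ph} \cdot 100 / V_{ph}$. Note that
$\%\mathrm{Gas}_{ph} \equiv -\mathrm{MLA}_{ph}/10$ algebraically; the
test-suite uses this identity as a self-check.

The linear air-fraction model assumes lung voxels are a two-component
air/tissue mixture on the HU scale anchored at air = −1000 HU and
tissue/water ≈ 0 HU. A region with MLA > 0 HU (possible in consolidated
lungs with dense lesions or calcification) yields a *negative* air
volume; we report it with a warning rather than flooring at zero, so the
conservation identities ($\mathrm{Tissue} + \mathrm{FRC} = V_{P02}$,
$\mathrm{TV} = \mathrm{Air} - \mathrm{FRC}$) stay exact.

## Aeration compartments

Murine parenchyma is partitioned by preclinical HU ranges:
normo-aerated $[-860, -435]$, hypo-aerated $(-435, -121)$, non-aerated
$[-121, 121]$. We honor the bracket notation literally, so the tie at
−435 HU belongs to normo and the tie at −121 HU to non. Two
denominator-related choices are deliberate:

* The denominator is *all* voxels of the selected region, and voxels
  outside the three ranges (hyper-aerated below −860 HU, dense above
  121 HU) form an explicit fourth `other` class. The three printed
  percentages therefore need not sum to 100; forcing a three-way
  partition would silently reassign hyper-aerated voxels.
* Compartments are reported from P02 by default (expiration is the
  phase in which aeration loss is most visible); `compartment_phase`
  switches to P01.

HU values outside the physically plausible $[-1000, 3000]$ band are
retained, not clamped — clamping would bias MLA — but counted
(`n_extreme_hu`) and flagged at load time.

# The synthetic phantom

No public scan data exist for this kind of study, so the package ships a
paired-phase thorax phantom with exact per-voxel ground truth. What it
emulates:

* **Geometry.** Two ellipsoidal lobes inside a soft-tissue body
  ellipse; the left lobe's radii are scaled so its volume share is
  `left_fraction` (default 1/3, the murine left lobe's share). The
  realized share at 64³ voxels lands within a few percent of target.
* **Compartments with exact truth.** Target fractions (`normo`, `hypo`,
  `non`, remainder `other`) are converted to voxel quotas; per-voxel HU
  is drawn from a Gaussian *truncated to that compartment's own HU
  range* (means −647.5 / −278 / 0 / −930 HU, sd 50 HU by default, open
  intervals shrunk by a hair so boundary ties cannot leak). Truncation
  is what makes the generator's labels an exact ground truth; with
  untruncated noise the "true" fraction would be ill-defined.
* **Lesion placement.** Lesion mass (non, then hypo) is split between
  the lobes by quota — proportional to lobe size, times a symmetric
  log-normal per-animal lobe effect (`lobe_noise_sd`, default 0.25),
  times $e^{b}$ for the left lobe where $b$ = `lesion_left_bias`.
  Within each lobe, voxels are ranked by a propensity field: an apical
  gradient (`lesion_apical_bias`, default 2) plus Gaussian lesion
  nuclei (`n_blobs` = 8, width 0.18 of the grid) plus voxel noise.
  The quota design matters: an earlier draft ranked one propensity
  field globally across both lobes, and the interaction of lumpy blob
  fields with unequal lobe sizes made the left-minus-right difference
  skewed and non-null even for unbiased settings (paired-test type-I
  error ≈ 0.18). Allocating quotas per lobe makes the two lobes
  exchangeable whenever the left bias is zero — the difference of two
  i.i.d. log-normal lobe effects is symmetric — which is exactly the
  property a calibrated paired left/right test needs.
* **Paired phases.** P01 is derived from P02 by scaling the lobe radii
  (`inspiration_volume_gain`, default 0.3) and shifting aerated-voxel
  HU down by `inspiration_air_gain` (default 150 HU), with lesion
  nuclei and lobe effects shared between phases. Deriving P01 from P02
  guarantees a coherent animal and a positive tidal volume; real
  acquisitions reconstruct the phases independently, which the phantom
  does not attempt to model.
* **Cohorts.** `default_cohort_design()` encodes a 4/7/12-animal
  SAL/BLM/BLM+NINT study over days 7/14/21. Trajectory anchors are the
  compartment percentages of representative study animals (SAL stable
  at ≈ 81/19/0; BLM %Non rising 1.5 → 38.9 with the day-14 value
  interpolated; the treated arm attenuated at 6.2 → 12.2) plus an
  early inflammatory volume gain decaying over time. Each animal gets
  a persistent log-normal random effect on its targets
  (`subject_sd` = 0.15) and volume (`volume_sd` = 0.05), and its own
  seed stream derived by hashing the cohort seed with the subject id,
  so regeneration is order-independent.

What the phantom does **not** emulate: airway trees, vessels, cardiac
motion, reconstruction artifacts, mask errors, or independent phase
reconstructions. Passing tests therefore demonstrate correctness of the
quantification given a faithful mask, not robustness to segmentation or
acquisition pathology.

# Statistics

* **Normalization.** Each biomarker is divided by the pooled control
  (SAL) mean over all days for the same region and biomarker; the
  normalized SAL mean is 1 by construction. `%Non` is excluded — it is
  essentially zero in healthy lungs, so its control mean is no
  denominator — and reported as absolute percentage.
* **Longitudinal model.** Ordinary two-way ANOVA (`lm(value ~ group *
  day)`, day categorical) on per-subject values. A repeated-measures
  structure would also be defensible since animals are scanned at all
  three days; we deliberately fit the ordinary model and treat the
  choice as a documented design decision rather than an inference about
  upstream practice. Post-hoc: Šidák-adjusted within-group
  day-21-vs-day-7 contrasts (adjusted across groups,
  $p' = 1-(1-p)^k$), and per-day Dunnett contrasts of every arm versus
  BLM via `emmeans` (the deterministic `dunnettx` approximation of the
  equicoordinate multivariate-t quantile, chosen over the Monte-Carlo
  integral so equal-seed runs are bit-identical; adjusted p is clamped
  to be ≥ raw p). Group summaries are mean ± SEM.
* **Percent inhibition/recovery.** Signed change of the treated-arm
  mean versus the disease-arm mean at day 21,
  $100(\bar x_{NINT} - \bar x_{BLM})/\bar x_{BLM}$, labeled recovery
  (+) or inhibition (−). The alternative convention relative to the
  disease-minus-control delta is available
  (`convention = "vs_disease_delta"`).
* **Paired lobe tests.** Shapiro–Wilk on the paired differences at
  α = 0.05 gates between the paired t-test and the Wilcoxon signed-rank
  test (normal approximation). All-zero differences short-circuit to
  "no difference" (p = 1); constant non-zero differences have zero
  variance and are flagged degenerate rather than forced through a
  t-test.
* **Histology.** Ashcroft field scores (0–8) are pooled per region —
  whole lung pools both lobes' fields so every field keeps equal
  weight — into a mean score and severity-class frequencies (no/mild
  0–3, moderate 4, severe ≥ 5; the three percentages always total
  100). Spearman correlation (average ranks, two-sided p) links
  day-21 biomarkers to the mean score; entries with p ≥ 0.05 are
  flagged `masked` for heat-map display but retained in the output.
  The synthetic score generator maps ground-truth %Non through the
  saturating curve $8x/(x + 0.25)$ and draws noisy integer fields
  around it — a monotone link for testing sign recovery, not a fitted
  model.

# Numerical and interface choices

* NIfTI IO via `RNifti`; volumes stored float32, masks uint8. The
  affine is never used for computation (all quantities are
  orientation-invariant); anisotropic headers are rejected unless
  explicitly accepted, in which case the geometric-mean voxel edge
  preserves voxel volume.
* Histograms use half-open bins $[l, r)$ of configurable width
  (default 10 HU) spanning the observed range, last bin closed, so
  counts always total $N$.
* Truncated Gaussians are sampled by inverse-CDF, which is exact and
  vectorized; sd = 0 degenerates to the mean, giving noiseless
  phantoms whose biomarkers equal ground truth bit for bit.
* Every orchestrated run writes its configuration hash (32-bit FNV-1a
  over the JSON-serialized scientific parameters, excluding filesystem
  paths) into each output CSV header and `run_manifest.json`, and a
  fixed seed reproduces the whole bundle bit-identically.

## Problem sizes in the test-suite

Unit tests use 16³–32³ phantoms. The ground-truth recovery check runs
the full 23-animal × 3-day cohort at 64³; statistical calibration uses
500 null cohorts of 8 animals and 100 left-biased cohorts of 10 animals
at 20³ — sizes chosen to keep the whole suite in the low minutes on a
laptop while leaving the measured properties (recovery within ±2
percentage points; paired-test type-I in [0.03, 0.07]; correct-sign
power ≥ 90%) well resolved.

# Known limitations

* The air-fraction model is linear in HU and anchored at fixed
  calibration points; scanner drift or beam hardening are out of scope.
* The phantom's lesion morphology (Gaussian nuclei) is a free modeling
  choice, not fitted to any measured lesion-shape statistics.
* The ANOVA ignores within-animal correlation across days; with 3 days
  and small groups a mixed model would have limited leverage, but
  p-values for between-day contrasts are approximate in that respect.
* Negative air volumes are physically impossible and indicate either
  extreme consolidation or calibration problems; they are flagged, and
  downstream summaries include them as-is.
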