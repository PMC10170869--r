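test_that("lung volume is voxel count times voxel cell volume", {
  v <- toy_volume(rep(-600, 1000), dims = c(10, 10, 10), voxel_size_mm = 0.05)
  expect_equal(lung_volume(v, 1:1000), 1000 * 0.05^3)  # = 0.125 mm^3

  v1 <- toy_volume(-600, dims = c(1, 1, 1), voxel_size_mm = 1)
  expect_equal(lung_volume(v1, 1L), 1)

  v8 <- toy_volume(rep(-600, 512), dims = c(8, 8, 8), voxel_size_mm = 0.05)
  expect_equal(lung_volume(v8, seq_len(512)), 0.064)

  expect_error(lung_volume(v, integer(0)), class = "fibroct_empty_region")
})

test_that("mean lung attenuation matches a naive summation oracle", {
  v <- toy_volume(rep(-1000, 27), dims = c(3, 3, 3))
  expect_equal(mean_lung_attenuation(v, 1:27), -1000)

  v2 <- toy_volume(c(-800, -400), dims = c(2, 1, 1))
  expect_equal(mean_lung_attenuation(v2, 1:2), -600)

  set.seed(3)
  vals <- rnorm(125, -500, 300)
  v3 <- toy_volume(vals, dims = c(5, 5, 5))
  expect_equal(mean_lung_attenuation(v3, 1:125), naive_mla(vals))

  expect_error(mean_lung_attenuation(v, integer(0)), class = "fibroct_empty_region")
})

test_that("air volume follows the densitometric formula, flagging MLA > 0", {
  expect_equal(air_volume(0.125, -1000), 0.125)  # fully aerated: Air = V
  expect_equal(air_volume(0.125, 0), 0)          # water density: no air
  expect_equal(air_volume(100, -500), 50)
  expect_warning(neg <- air_volume(1, 50), "negative air")
  expect_equal(neg, -0.05)
  expect_error(air_volume(-1, -500), class = "fibroct_validation_error")
})

test_that("aeration classification honors the bracket convention at every boundary", {
  cls <- function(hu) as.character(classify_aeration(hu))
  expect_equal(cls(-860), "normo")   # closed lower bound of normo
  expect_equal(cls(-435), "normo")   # closed upper bound of normo
  expect_equal(cls(-434.999), "hypo")
  expect_equal(cls(-121.001), "hypo")
  expect_equal(cls(-121), "non")     # closed lower bound of non
  expect_equal(cls(121), "non")      # closed upper bound of non
  expect_equal(cls(-900), "other")   # hyper-aerated
  expect_equal(cls(-860.001), "other")
  expect_equal(cls(121.001), "other")
  expect_equal(cls(2000), "other")
})

test_that("compartment fractions match brute-force classification", {
  toy <- c(-900, -800, -700, -500, -300, -200, -100, 0)
  v <- toy_volume(toy, dims = c(2, 2, 2))
  f <- compartment_fractions(v, 1:8)
  expect_equal(unname(f), c(37.5, 25, 25, 12.5))

  vconst <- toy_volume(rep(-600, 8), dims = c(2, 2, 2))
  expect_equal(unname(compartment_fractions(vconst, 1:8)), c(100, 0, 0, 0))

  expect_error(compartment_fractions(v, integer(0)), class = "fibroct_empty_region")
})

test_that("vectorized operations equal naive-loop oracles on random fields", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:1000, 1)
    vals <- round(runif(n, -1100, 300), 1)
    side <- ceiling(n^(1 / 3))
    v <- toy_volume(vals, dims = c(side, side, ceiling(n / side^2)))
    idx <- seq_len(n)
    expect_equal(mean_lung_attenuation(v, idx), naive_mla(vals))
    expect_equal(unname(compartment_fractions(v, idx)), unname(naive_fractions(vals)))
    bw <- sample(c(10, 25, 50, 100), 1)
    h <- hu_histogram(v, idx, bin_width = bw)
    expect_identical(h$count, naive_histogram(vals, bw))
    expect_equal(sum(h$count), n)
  }
})

test_that("HU histograms use half-open bins with a closed last bin", {
  v <- toy_volume(c(-1000, -1000, -500, 0), dims = c(4, 1, 1))
  h <- hu_histogram(v, 1:4, bin_width = 500)
  expect_equal(h$count, c(2L, 2L))
  expect_equal(h$bin_left, c(-1000, -500))
  expect_equal(h$bin_right, c(-500, 0))

  hc <- hu_histogram(toy_volume(rep(-650, 30), dims = c(30, 1, 1)), 1:30, 10)
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$count, 30L)

  expect_error(hu_histogram(v, 1:4, bin_width = 0), class = "fibroct_validation_error")
})

test_that("functional biomarkers evaluate all formulas on a constant-phase pair", {
  # V_P01 = 0.2 mm^3 and V_P02 = 0.1 mm^3 at 0.05 mm voxels
  pair <- constant_pair(hu_p01 = -1000, n_p01 = 1600, hu_p02 = -500, n_p02 = 800)
  rec <- functional_biomarkers(pair, "whole")
  expect_equal(rec$V_P01, 0.2)
  expect_equal(rec$V_P02, 0.1)
  expect_equal(rec$Air, 0.2)       # fully aerated P01
  expect_equal(rec$FRC, 0.05)
  expect_equal(rec$TV, 0.15)
  expect_equal(rec$Tissue, 0.05)
  expect_equal(rec$pct_gas_P01, 100)
  expect_equal(rec$pct_gas_P02, 50)
  # P02 at -500 HU is entirely normo-aerated
  expect_equal(rec$pct_normo, 100)
})

test_that("identical phases give zero tidal volume and %Gas = -MLA/10", {
  set.seed(5)
  spec <- phantom_spec(shape = c(24, 24, 24), seed = 9)
  subj <- generate_subject(spec)
  p02 <- subj$pair$p02
  p01v <- ct_volume(p02$volume$data, p02$volume$voxel_size_mm, "P01",
                    p02$volume$subject_id, p02$volume$day)
  pair <- subject_scan_pair(p01v, lung_mask(p02$mask$labels, p01v),
                            p02$volume, p02$mask)
  rec <- functional_biomarkers(pair, "whole")
  expect_equal(rec$TV, 0)

  real <- functional_biomarkers(subj$pair, "whole")
  expect_equal(real$pct_gas_P01, -real$MLA_P01 / 10)
  expect_equal(real$pct_gas_P02, -real$MLA_P02 / 10)
})

test_that("raising a voxel's HU weakly increases MLA and decreases air", {
  set.seed(7)
  vals <- rnorm(64, -600, 150)
  side <- 4
  for (i in 1:10) {
    j <- sample(64, 1)
    bumped <- vals; bumped[j] <- bumped[j] + runif(1, 1, 300)
    v0 <- toy_volume(vals, dims = c(side, side, side))
    v1 <- toy_volume(bumped, dims = c(side, side, side))
    mla0 <- mean_lung_attenuation(v0, 1:64)
    mla1 <- mean_lung_attenuation(v1, 1:64)
    expect_gt(mla1, mla0)
    expect_lt(air_volume(0.064, mla1), air_volume(0.064, mla0))
  }
})

test_that("conservation identities hold on generated subjects", {
  subj <- generate_subject(phantom_spec(shape = c(24, 24, 24),
                                        compartment_targets = c(normo = 0.6, hypo = 0.25, non = 0.1),
                                        seed = 13))
  for (rg in c("whole", "left", "right")) {
    rec <- suppressWarnings(functional_biomarkers(subj$pair, rg))
    expect_equal(rec$Tissue + rec$FRC, rec$V_P02)
    expect_equal(rec$TV, rec$Air - rec$FRC)
    expect_equal(rec$pct_normo + rec$pct_hypo + rec$pct_non + rec$pct_other, 100)
  }
})
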