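test_that("control normalization divides by the pooled control mean", {
  tab <- rbind(
    toy_study_table(list(SAL = c(1.8, 2.2)), biomarker = "Tissue", day = 7),
    toy_study_table(list(BLM = 3.0), biomarker = "Tissue", day = 21))
  tab$subject_id <- paste0(tab$group, seq_len(nrow(tab)))
  norm <- normalize_to_control(tab)
  expect_equal(norm$value[norm$group == "BLM"], 1.5)   # 3.0 / mean(1.8, 2.2)
  expect_equal(mean(norm$value[norm$group == "SAL"]), 1.0)
})

test_that("the non-aerated percentage passes through normalization unchanged", {
  tab <- rbind(
    toy_study_table(list(SAL = c(0.1, 0.2), BLM = c(30, 40)), biomarker = "pct_non"),
    toy_study_table(list(SAL = c(2, 3), BLM = c(5, 6)), biomarker = "Tissue"))
  tab$subject_id <- paste0(tab$group, "_", seq_len(nrow(tab)))
  norm <- normalize_to_control(tab)
  expect_equal(norm$value[norm$biomarker == "pct_non"],
               tab$value[tab$biomarker == "pct_non"])
  expect_false(any(norm$normalized[norm$biomarker == "pct_non"]))
})

test_that("normalization is invariant to rescaling the raw values", {
  set.seed(9)
  tab <- toy_study_table(list(SAL = runif(4, 1, 2), BLM = runif(5, 2, 4),
                              `BLM+NINT` = runif(5, 1.5, 3)), biomarker = "TV")
  tab$subject_id <- paste0(tab$group, "_", seq_len(nrow(tab)))
  scaled <- tab; scaled$value <- tab$value * 7.3
  expect_equal(normalize_to_control(tab)$value, normalize_to_control(scaled)$value)
})

test_that("normalization errors are informative", {
  tab <- toy_study_table(list(BLM = c(1, 2)), biomarker = "TV")
  expect_error(normalize_to_control(tab), class = "fibroct_normalization_error")
  tab0 <- toy_study_table(list(SAL = c(0, 0), BLM = c(1, 2)), biomarker = "TV")
  err <- expect_error(normalize_to_control(tab0), class = "fibroct_normalization_error")
  expect_match(conditionMessage(err), "TV")
})

test_that("percent change versus the disease arm follows the signed convention", {
  tab <- toy_study_table(list(BLM = 40, `BLM+NINT` = 17.2))
  res <- percent_change_vs_blm(tab, "pct_non", "whole")
  expect_equal(res$percent, -57)
  expect_equal(res$label, "inhibition")

  tab2 <- toy_study_table(list(BLM = 5, `BLM+NINT` = 5))
  expect_equal(percent_change_vs_blm(tab2, "pct_non", "whole")$percent, 0)

  tab3 <- toy_study_table(list(BLM = 0.6, `BLM+NINT` = 0.798), biomarker = "pct_normo")
  res3 <- percent_change_vs_blm(tab3, "pct_normo", "whole")
  expect_equal(res3$percent, 33)
  expect_equal(res3$label, "recovery")

  tab4 <- toy_study_table(list(BLM = 0, `BLM+NINT` = 1))
  expect_error(percent_change_vs_blm(tab4, "pct_non", "whole"),
               class = "fibroct_undefined_change")

  # delta convention: change relative to the disease-minus-control gap
  tab5 <- rbind(toy_study_table(list(SAL = c(1, 1), BLM = c(3, 3), `BLM+NINT` = c(2, 2)),
                                biomarker = "Tissue"))
  tab5$subject_id <- paste0(tab5$group, "_", seq_len(nrow(tab5)))
  res5 <- percent_change_vs_blm(tab5, "Tissue", "whole", convention = "vs_disease_delta")
  expect_equal(res5$percent, 50)  # recovered half the disease delta
})

test_that("groups with identical values yield null contrasts", {
  vals <- c(1.0, 1.2, 0.9, 1.1)
  tab <- do.call(rbind, lapply(c(7, 14, 21), function(d)
    toy_study_table(list(BLM = vals, `BLM+NINT` = vals), biomarker = "TV", day = d)))
  tab$subject_id <- paste0(tab$group, "_", rep(1:4, times = 6))
  es <- longitudinal_tests(tab, "TV", "whole")
  expect_true(all(abs(es$between$estimate) < 1e-12))
  expect_true(all(es$between$p_dunnett > 0.999))
})

test_that("adjusted p-values never fall below raw p-values", {
  set.seed(15)
  for (i in 1:10) {
    tab <- do.call(rbind, lapply(c(7, 14, 21), function(d)
      toy_study_table(list(SAL = rnorm(4, 1, .2), BLM = rnorm(5, 1.5, .2),
                           `BLM+NINT` = rnorm(5, 1.2, .2)),
                      biomarker = "Tissue", day = d)))
    tab$subject_id <- paste(tab$group, rep(seq_len(14), times = 3))
    es <- longitudinal_tests(tab, "Tissue", "whole")
    expect_true(all(es$between$p_dunnett >= es$between$p_raw - 1e-12))
    expect_true(all(es$within$p_sidak >= es$within$p_raw - 1e-12))
  }
})

test_that("a strong generated progression is detected in the disease arm", {
  set.seed(22)
  # emulate a day-7 -> day-21 rise of the non-aerated fraction
  tab <- rbind(
    toy_study_table(list(SAL = abs(rnorm(4, 0.2, 0.1)), BLM = rnorm(7, 2, 1),
                         `BLM+NINT` = rnorm(12, 2, 1)), day = 7),
    toy_study_table(list(SAL = abs(rnorm(4, 0.2, 0.1)), BLM = rnorm(7, 20, 4),
                         `BLM+NINT` = rnorm(12, 8, 3)), day = 14),
    toy_study_table(list(SAL = abs(rnorm(4, 0.2, 0.1)), BLM = rnorm(7, 39, 5),
                         `BLM+NINT` = rnorm(12, 12, 4)), day = 21))
  tab$subject_id <- paste(tab$group, rep(seq_len(23), times = 3))
  es <- longitudinal_tests(tab, "pct_non", "whole")
  blm <- es$within[es$within$group == "BLM", ]
  expect_gt(blm$estimate, 0)
  expect_lt(blm$p_sidak, 0.05)
  d21 <- es$between[es$between$day == 21 & grepl("NINT", es$between$contrast), ]
  expect_lt(d21$estimate, 0)
  expect_lt(d21$p_dunnett, 0.05)
})

test_that("empty design cells degrade with a warning", {
  tab <- rbind(
    toy_study_table(list(BLM = c(1, 2, 3), `BLM+NINT` = c(1.5, 2.5, 3.5)), day = 7),
    toy_study_table(list(BLM = c(2, 3, 4)), day = 21))
  tab$subject_id <- paste(tab$group, seq_len(nrow(tab)))
  w <- capture_warnings(es <- longitudinal_tests(tab, "pct_non", "whole"))
  expect_true(any(grepl("estimable|subjects", w)))
  expect_s3_class(es, "effect_summary")
})

test_that("paired lobe test gates on normality and handles degeneracy", {
  # identical lobes: no difference
  t1 <- toy_lobe_table(left = c(1, 2, 3, 4, 5), right = c(1, 2, 3, 4, 5))
  r1 <- paired_lobe_test(t1, "pct_non", "BLM", 21)
  expect_equal(r1$test_used, "no_difference")
  expect_equal(r1$p_value, 1)

  # constant non-zero offset: zero-variance degenerate
  t2 <- toy_lobe_table(left = c(6, 7, 8, 9, 10), right = c(1, 2, 3, 4, 5))
  expect_warning(r2 <- paired_lobe_test(t2, "pct_non", "BLM", 21), "degenerate")
  expect_equal(r2$test_used, "degenerate")
  expect_true(is.na(r2$p_value))

  # constant offset with tiny noise: strongly significant paired t at n = 5
  set.seed(33)
  right <- rnorm(5, 10, 1)
  t3 <- toy_lobe_table(left = right + 5 + rnorm(5, 0, 0.01), right = right)
  r3 <- paired_lobe_test(t3, "pct_non", "BLM", 21)
  expect_equal(r3$test_used, "paired_t")
  expect_lt(r3$p_value, 0.05)
  expect_gt(r3$mean_difference, 0)

  expect_error(paired_lobe_test(toy_lobe_table(1:2, 3:4), "pct_non", "BLM", 21),
               class = "fibroct_insufficient_data")
})

test_that("heavy-tailed differences are routed to the Wilcoxon branch", {
  set.seed(44)
  used <- replicate(40, {
    right <- rnorm(12, 10, 0.5)
    left <- right + rcauchy(12, 0, 2)   # Cauchy-contaminated differences
    tab <- toy_lobe_table(left, right)
    paired_lobe_test(tab, "pct_non", "BLM", 21)$test_used
  })
  expect_gt(mean(used == "wilcoxon"), 0.5)
})

test_that("the lobe significance matrix tabulates stars per group-day", {
  set.seed(55)
  tabs <- list()
  for (d in c(7, 21)) for (g in c("BLM", "BLM+NINT")) {
    right <- rnorm(6, 10, 1)
    shift <- if (d == 21) 4 else 0
    tabs[[paste(d, g)]] <- toy_lobe_table(right + shift + rnorm(6, 0, 0.5), right,
                                          group = g, day = d)
  }
  tab <- do.call(rbind, tabs)
  mat <- lobe_significance_matrix(tab, biomarkers = "pct_non", days = c(7, 21))
  expect_equal(nrow(mat), 1)
  expect_equal(mat$day7_BLM, "ns")
  expect_true(mat$day21_BLM %in% c("*", "**", "***"))
})
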