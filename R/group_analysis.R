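#' Reshape a biomarker table into a long study table
#'
#' The study table is the unit of statistical analysis: one row per
#' (subject, group, day, region, biomarker, value).
#'
#' @param biomarkers wide per-region biomarker data.frame from
#'   \code{\link{compute_biomarkers}} (must carry a \code{group} column).
#' @param biomarker_cols which biomarker columns to carry into the long
#'   table; defaults to the morphological and functional endpoints of a
#'   longitudinal drug study.
#' @return A data.frame of class \code{study_table} with columns
#'   \code{subject_id}, \code{group}, \code{day}, \code{region},
#'   \code{biomarker}, \code{value}.
#' @export
as_study_table <- function(biomarkers,
                           biomarker_cols = c("pct_normo", "pct_hypo", "pct_non",
                                              "Tissue", "V_P02", "pct_gas_P01",
                                              "pct_gas_P02", "TV")) {
  need <- c("subject_id", "group", "day", "region", biomarker_cols)
  missing <- setdiff(need, names(biomarkers))
  if (length(missing) > 0L)
    stop_fibroct("fibroct_format_error",
                 sprintf("biomarker table lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  long <- do.call(rbind, lapply(biomarker_cols, function(bm) {
    data.frame(subject_id = biomarkers$subject_id, group = biomarkers$group,
               day = biomarkers$day, region = biomarkers$region,
               biomarker = bm, value = biomarkers[[bm]])
  }))
  key <- with(long, paste(subject_id, day, region, biomarker))
  if (anyDuplicated(key))
    stop_fibroct("fibroct_format_error",
                 "duplicate (subject, day, region, biomarker) rows in study table")
  rownames(long) <- NULL
  class(long) <- c("study_table", "data.frame")
  long
}

#' Normalize biomarkers to the control-group mean
#'
#' Divides every value by the pooled control (SAL) mean for the same
#' (region, biomarker), where the pool is all control subjects across all
#' study days; the normalized control mean is therefore 1 by construction.
#' The non-aerated percentage is excluded and passed through as an
#' absolute percentage, because it is essentially zero in healthy control
#' lungs and its control mean is no meaningful denominator.
#'
#' @param table a \code{\link{as_study_table}} study table.
#' @param control control group label (default \code{"SAL"}).
#' @param exclude biomarkers passed through unnormalized (default
#'   \code{"pct_non"}).
#' @return The study table with normalized \code{value}s and a logical
#'   \code{normalized} column.
#' @export
normalize_to_control <- function(table, control = "SAL", exclude = "pct_non") {
  if (!control %in% table$group)
    stop_fibroct("fibroct_normalization_error",
                 sprintf("control group '%s' absent from table", control))
  out <- table
  out$normalized <- !(out$biomarker %in% exclude)
  for (rg in unique(table$region)) {
    for (bm in setdiff(unique(table$biomarker), exclude)) {
      sel <- table$region == rg & table$biomarker == bm
      ctrl_vals <- table$value[sel & table$group == control]
      if (length(ctrl_vals) == 0L || all(is.na(ctrl_vals)))
        stop_fibroct("fibroct_normalization_error",
                     sprintf("no control values for biomarker '%s' in region '%s'", bm, rg))
      m <- mean(ctrl_vals, na.rm = TRUE)
      if (m == 0)
        stop_fibroct("fibroct_normalization_error",
                     sprintf("control mean is 0 for biomarker '%s' in region '%s'", bm, rg))
      out$value[sel] <- table$value[sel] / m
    }
  }
  class(out) <- class(table)
  out
}

#' Percent inhibition or recovery of the treated arm versus disease arm
#'
#' Signed relative change of the treated-group mean versus the
#' disease-group mean at the stated day,
#' \eqn{100 (\bar{x}_{treated} - \bar{x}_{disease}) / \bar{x}_{disease}}.
#' A positive value is labeled \code{"recovery"} (the parameter is
#' restored towards control), a negative one \code{"inhibition"} (disease
#' progression is suppressed). The alternative convention — change
#' relative to the disease-minus-control delta,
#' \eqn{100 (\bar{x}_{treated} - \bar{x}_{disease}) /
#' (\bar{x}_{control} - \bar{x}_{disease})} — is available via
#' \code{convention = "vs_disease_delta"}.
#'
#' @param table a study table (normalized or raw).
#' @param biomarker,region endpoint to summarize.
#' @param day study day (default 21, the treatment end).
#' @param disease,treated,control group labels.
#' @param convention \code{"vs_blm"} (default) or \code{"vs_disease_delta"}.
#' @return A list with \code{percent} (signed \%), \code{label}
#'   (\code{"recovery"}/\code{"inhibition"}/\code{"no_change"}) and the
#'   group means used.
#' @export
percent_change_vs_blm <- function(table, biomarker, region, day = 21,
                                  disease = "BLM", treated = "BLM+NINT",
                                  control = "SAL",
                                  convention = c("vs_blm", "vs_disease_delta")) {
  convention <- match.arg(convention)
  pick <- function(grp) {
    v <- table$value[table$group == grp & table$day == day &
                       table$region == region & table$biomarker == biomarker]
    if (length(v) == 0L)
      stop_fibroct("fibroct_design_error",
                   sprintf("no values for group '%s' at day %s (%s, %s)",
                           grp, day, biomarker, region))
    mean(v, na.rm = TRUE)
  }
  m_dis <- pick(disease)
  m_trt <- pick(treated)
  if (convention == "vs_blm") {
    if (m_dis == 0)
      stop_fibroct("fibroct_undefined_change", "disease-group mean is 0; percent change undefined")
    pct <- 100 * (m_trt - m_dis) / m_dis
  } else {
    m_ctl <- pick(control)
    if (m_ctl == m_dis)
      stop_fibroct("fibroct_undefined_change", "control and disease means equal; delta undefined")
    pct <- 100 * (m_trt - m_dis) / (m_ctl - m_dis)
  }
  label <- if (pct > 0) "recovery" else if (pct < 0) "inhibition" else "no_change"
  list(percent = pct, label = label,
       mean_disease = m_dis, mean_treated = m_trt, convention = convention)
}

sidak_adjust <- function(p, k = length(p)) pmin(1, 1 - (1 - p)^k)

#' Longitudinal two-way ANOVA with post-hoc contrasts
#'
#' Fits an ordinary two-way (group x day, day categorical) ANOVA to one
#' biomarker/region and reports the drug-study contrasts: Sidak-adjusted
#' within-group day-21-versus-day-7 changes, and Dunnett-adjusted per-day
#' comparisons of every other group against the disease (BLM) reference.
#' Group means are summarized as mean +/- SEM per day. Empty design cells
#' degrade to the estimable contrasts with a warning.
#'
#' @param table a study table, typically after
#'   \code{\link{normalize_to_control}}.
#' @param biomarker,region endpoint to analyse.
#' @param reference reference (disease) group for Dunnett contrasts.
#' @param day_contrast the two days contrasted within groups (default
#'   \code{c(7, 21)}).
#' @return An object of class \code{effect_summary}: a list with
#'   \code{means} (group/day mean, sem, n), \code{within} (per-group
#'   day-contrast estimate, raw and Sidak-adjusted p), \code{between}
#'   (per-day contrasts vs the reference with raw and Dunnett-adjusted p),
#'   \code{anova} (the two-way ANOVA table) and metadata.
#' @export
longitudinal_tests <- function(table, biomarker, region, reference = "BLM",
                               day_contrast = c(7, 21)) {
  df <- table[table$biomarker == biomarker & table$region == region &
                !is.na(table$value), ]
  if (nrow(df) == 0L)
    stop_fibroct("fibroct_design_error",
                 sprintf("no data for biomarker '%s' in region '%s'", biomarker, region))
  df$group <- factor(df$group)
  df$day_f <- factor(df$day)
  cell_n <- table(df$group, df$day_f)
  if (any(cell_n < 2L))
    warning(sprintf("design cell(s) with < 2 subjects: %s; contrasts degrade to what is estimable",
                    paste(apply(which(cell_n < 2L, arr.ind = TRUE), 1L, function(ij)
                      paste0(rownames(cell_n)[ij[1]], "/day", colnames(cell_n)[ij[2]])),
                      collapse = ", ")))
  fit <- stats::lm(value ~ group * day_f, data = df)
  aov_tab <- stats::anova(fit)

  means <- do.call(rbind, lapply(split(df, list(df$group, df$day_f), drop = TRUE),
    function(d) data.frame(group = as.character(d$group[1]), day = d$day[1],
                           mean = mean(d$value),
                           sem = stats::sd(d$value) / sqrt(nrow(d)),
                           n = nrow(d))))
  rownames(means) <- NULL
  means <- means[order(means$group, means$day), ]

  # within-group day_contrast[2] vs day_contrast[1], Sidak over groups
  within <- NULL
  emm_day <- try(emmeans::emmeans(fit, ~ day_f | group), silent = TRUE)
  if (!inherits(emm_day, "try-error")) {
    lev <- levels(df$day_f)
    w <- numeric(length(lev))
    w[lev == as.character(day_contrast[1])] <- -1
    w[lev == as.character(day_contrast[2])] <- 1
    if (sum(w != 0) == 2L) {
      ct <- emmeans::contrast(emm_day, method = stats::setNames(
        list(w), sprintf("day%s - day%s", day_contrast[2], day_contrast[1])))
      s <- as.data.frame(summary(ct))
      within <- data.frame(group = as.character(s$group), estimate = s$estimate,
                           p_raw = s$p.value,
                           p_sidak = sidak_adjust(s$p.value, nrow(s)))
    }
  }

  # per-day contrasts vs the reference group, Dunnett-adjusted
  between <- NULL
  if (reference %in% levels(df$group) && nlevels(df$group) >= 2L) {
    emm_grp <- emmeans::emmeans(fit, ~ group | day_f)
    ct <- emmeans::contrast(emm_grp, "trt.vs.ctrl",
                            ref = which(levels(df$group) == reference),
                            adjust = "dunnettx")
    raw <- emmeans::contrast(emm_grp, "trt.vs.ctrl",
                             ref = which(levels(df$group) == reference),
                             adjust = "none")
    s <- as.data.frame(summary(ct))
    sr <- as.data.frame(summary(raw))
    between <- data.frame(day = as.numeric(as.character(s$day_f)),
                          contrast = as.character(s$contrast),
                          estimate = s$estimate,
                          p_raw = sr$p.value,
                          p_dunnett = pmax(s$p.value, sr$p.value))
    between <- between[stats::complete.cases(between[c("estimate")]), ]
    if (anyNA(s$p.value))
      warning("some between-group contrasts were not estimable and were dropped")
  }

  structure(list(biomarker = biomarker, region = region, reference = reference,
                 means = means, within = within, between = between,
                 anova = aov_tab),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("<effect_summary> %s (%s lung), reference %s\n",
              x$biomarker, x$region, x$reference))
  cat("group means (mean +/- SEM):\n"); print(x$means, digits = 4)
  if (!is.null(x$within)) { cat("within-group day contrasts (Sidak):\n"); print(x$within, digits = 4) }
  if (!is.null(x$between)) { cat("between-group contrasts (Dunnett):\n"); print(x$between, digits = 4) }
  invisible(x)
}

#' Paired left-versus-right lobe test
#'
#' Pairs each subject's left and right lobe values for one biomarker,
#' group and day, gates on normality of the paired differences
#' (Shapiro-Wilk at the stated alpha) and applies the paired Student
#' t-test when the differences look normal, otherwise the Wilcoxon
#' signed-rank test. All-zero differences are reported as
#' \code{"no_difference"} (p = 1); constant non-zero differences have zero
#' variance and are flagged \code{"degenerate"} rather than forced through
#' a t-test.
#'
#' @param table a study table containing \code{left} and \code{right}
#'   region rows.
#' @param biomarker,group,day cell to test.
#' @param shapiro_alpha significance level of the normality gate
#'   (default 0.05).
#' @return A list with \code{statistic}, \code{p_value}, \code{test_used}
#'   (\code{"paired_t"}, \code{"wilcoxon"}, \code{"no_difference"} or
#'   \code{"degenerate"}), \code{n_pairs} and \code{mean_difference}
#'   (left minus right).
#' @export
paired_lobe_test <- function(table, biomarker, group, day, shapiro_alpha = 0.05) {
  sel <- table$biomarker == biomarker & table$group == group & table$day == day
  lft <- table[sel & table$region == "left", c("subject_id", "value")]
  rgt <- table[sel & table$region == "right", c("subject_id", "value")]
  m <- merge(lft, rgt, by = "subject_id", suffixes = c("_left", "_right"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3L)
    stop_fibroct("fibroct_insufficient_data",
                 sprintf("only %d complete left/right pairs (need >= 3)", nrow(m)))
  d <- m$value_left - m$value_right
  out <- list(n_pairs = nrow(m), mean_difference = mean(d))
  if (all(d == 0)) {
    out$statistic <- 0; out$p_value <- 1; out$test_used <- "no_difference"
    return(out)
  }
  if (stats::sd(d) == 0) {
    out$statistic <- NA_real_; out$p_value <- NA_real_; out$test_used <- "degenerate"
    warning("paired differences are a non-zero constant; zero variance, test degenerate")
    return(out)
  }
  normal_ok <- stats::shapiro.test(d)$p.value >= shapiro_alpha
  if (normal_ok) {
    tt <- stats::t.test(m$value_left, m$value_right, paired = TRUE)
    out$statistic <- unname(tt$statistic); out$p_value <- tt$p.value
    out$test_used <- "paired_t"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(m$value_left, m$value_right,
                                              paired = TRUE, exact = FALSE))
    out$statistic <- unname(wt$statistic); out$p_value <- wt$p.value
    out$test_used <- "wilcoxon"
  }
  out
}

#' Significance stars for a p-value
#'
#' \code{ns} for p >= 0.05, then \code{*}, \code{**}, \code{***} at 0.05,
#' 0.01 and 0.001.
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Paired-lobe significance matrix
#'
#' Runs \code{\link{paired_lobe_test}} for every biomarker over the given
#' groups and days and tabulates the significance stars: one row per
#' biomarker, one column per group-day cell.
#'
#' @param table a study table with left and right region rows.
#' @param biomarkers biomarkers to include (default: all in the table).
#' @param groups,days cells to test.
#' @return A data.frame with a \code{biomarker} column followed by one
#'   star column per (day, group).
#' @export
lobe_significance_matrix <- function(table, biomarkers = unique(table$biomarker),
                                     groups = c("BLM", "BLM+NINT"),
                                     days = c(7, 14, 21)) {
  cols <- list(biomarker = biomarkers)
  for (d in days) for (g in groups) {
    stars <- vapply(biomarkers, function(bm) {
      res <- try(paired_lobe_test(table, bm, g, d), silent = TRUE)
      if (inherits(res, "try-error") || is.na(res$p_value)) NA_character_
      else significance_stars(res$p_value)
    }, character(1))
    cols[[sprintf("day%d_%s", d, gsub("[^A-Za-z0-9]", "", g))]] <- stars
  }
  out <- as.data.frame(cols, check.names = FALSE)
  rownames(out) <- NULL
  out
}
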