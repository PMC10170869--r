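#' Severity class of an Ashcroft field score
#'
#' The ordinal Ashcroft score (0-8 per microscopic field) is collapsed
#' into three fibrosis severity classes: no/mild (0-3), moderate (exactly
#' 4) and severe (5 and above).
#'
#' @param score integer vector of field scores in 0..8.
#' @return Factor with levels \code{no_mild}, \code{moderate},
#'   \code{severe}.
#' @export
ashcroft_class <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 8) ||
      any(score != round(score)))
    stop_fibroct("fibroct_validation_error",
                 "Ashcroft scores must be integers in [0, 8]")
  cls <- ifelse(score <= 3, "no_mild", ifelse(score == 4, "moderate", "severe"))
  factor(cls, levels = c("no_mild", "moderate", "severe"))
}

#' Read a table of per-field Ashcroft scores
#'
#' @param path CSV with columns \code{subject_id}, \code{lobe}
#'   (\code{left}/\code{right}), \code{field_index}, \code{score}.
#' @return A validated data.frame.
#' @export
read_ashcroft <- function(path) {
  if (!file.exists(path))
    stop_fibroct("fibroct_io_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("subject_id", "lobe", "field_index", "score")
  if (!all(need %in% names(df)))
    stop_fibroct("fibroct_format_error",
                 sprintf("Ashcroft table lacks column(s): %s",
                         paste(setdiff(need, names(df)), collapse = ", ")))
  if (!all(df$lobe %in% c("left", "right")))
    stop_fibroct("fibroct_format_error", "lobe must be 'left' or 'right'")
  ashcroft_class(df$score)  # validates the range
  df
}

#' Summarize Ashcroft field scores for one region
#'
#' Mean field score and the severity-class frequency distribution. Whole
#' lung pools the fields of both lobes (the score is defined per field, so
#' pooling rather than averaging lobe means keeps every field equally
#' weighted).
#'
#' @param records data.frame of per-field scores (columns
#'   \code{subject_id}, \code{lobe}, \code{score}), usually one subject.
#' @param region \code{"whole"}, \code{"left"} or \code{"right"}.
#' @return A list with \code{mean_score}, \code{n_fields} and
#'   \code{distribution} (named percentages \code{no_mild},
#'   \code{moderate}, \code{severe}, summing to 100).
#' @export
ashcroft_summary <- function(records, region = c("whole", "left", "right")) {
  region <- match.arg(region)
  sel <- if (region == "whole") rep(TRUE, nrow(records)) else records$lobe == region
  scores <- records$score[sel]
  if (length(scores) == 0L)
    stop_fibroct("fibroct_empty_region",
                 sprintf("no Ashcroft fields for region '%s'", region))
  cls <- ashcroft_class(scores)
  dist <- 100 * as.vector(table(cls)) / length(scores)
  list(mean_score = mean(scores), n_fields = length(scores),
       distribution = stats::setNames(dist, levels(cls)))
}

#' Per-subject Ashcroft summary table
#'
#' @param records data.frame of per-field scores for many subjects.
#' @param regions regions to summarize.
#' @return A data.frame with one row per (subject, region): mean score,
#'   field count and class percentages.
#' @export
ashcroft_table <- function(records, regions = c("whole", "left", "right")) {
  rows <- list()
  for (sid in unique(records$subject_id)) {
    rec <- records[records$subject_id == sid, ]
    for (rg in regions) {
      s <- try(ashcroft_summary(rec, rg), silent = TRUE)
      if (inherits(s, "try-error")) next
      rows[[paste(sid, rg)]] <- data.frame(
        subject_id = sid, region = rg, mean_score = s$mean_score,
        n_fields = s$n_fields,
        pct_no_mild = s$distribution[["no_mild"]],
        pct_moderate = s$distribution[["moderate"]],
        pct_severe = s$distribution[["severe"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of imaging biomarkers with the Ashcroft score
#'
#' For each biomarker, Spearman's rank correlation (average-rank tie
#' handling, two-sided p) between the per-subject biomarker value in one
#' region and the subject's mean Ashcroft score in the same region,
#' typically at sacrifice (day 21). Entries that miss the significance
#' threshold are flagged \code{masked} for heat-map reporting but kept
#' unmasked in the table; constant vectors yield an undefined-correlation
#' flag instead of a coefficient.
#'
#' @param study a study table restricted to the correlation day.
#' @param histology per-subject summary from \code{\link{ashcroft_table}}.
#' @param region region to correlate.
#' @param day study day of the imaging values (default 21).
#' @param alpha masking threshold (default 0.05).
#' @return A data.frame with columns \code{biomarker}, \code{region},
#'   \code{R}, \code{p_value}, \code{n}, \code{masked}, \code{undefined}.
#' @export
spearman_matrix <- function(study, histology, region = "whole", day = 21,
                            alpha = 0.05) {
  hist_r <- histology[histology$region == region, c("subject_id", "mean_score")]
  rows <- lapply(unique(study$biomarker), function(bm) {
    img <- study[study$biomarker == bm & study$region == region &
                   study$day == day, c("subject_id", "value")]
    m <- merge(img, hist_r, by = "subject_id")
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < 3L)
      stop_fibroct("fibroct_insufficient_data",
                   sprintf("fewer than 3 subjects with both '%s' and Ashcroft data", bm))
    undef <- stats::sd(m$value) == 0 || stats::sd(m$mean_score) == 0
    if (undef) {
      R <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(m$value, m$mean_score,
                                             method = "spearman", exact = FALSE))
      R <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(biomarker = bm, region = region, R = R, p_value = p,
               n = nrow(m), masked = is.na(p) | p >= alpha, undefined = undef)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic Ashcroft scores from phantom ground truth
#'
#' Maps each subject's ground-truth non-aerated percentage through a
#' saturating monotone curve to an expected field score, then draws
#' integer field scores around it — a test harness for the
#' histology-imaging correlation, not a model fitted to any real scoring.
#' The expected score is \eqn{8 x / (x + half_sat)} for non-aerated
#' fraction \eqn{x} plus a lobe offset, with Gaussian field noise, rounded
#' and clamped to 0..8.
#'
#' @param truth_table per-region ground-truth biomarker rows (one
#'   \code{left} and one \code{right} row per subject) with
#'   \code{pct_non}.
#' @param n_fields fields scored per lobe (default 10).
#' @param half_sat non-aerated fraction (0-1 scale) at which the expected
#'   score reaches 4 (default 0.25).
#' @param noise_sd field-to-field score noise (default 0.8).
#' @param seed integer seed.
#' @return A per-field score data.frame as read by
#'   \code{\link{read_ashcroft}}.
#' @export
synthetic_ashcroft <- function(truth_table, n_fields = 10L, half_sat = 0.25,
                               noise_sd = 0.8, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lobes <- truth_table[truth_table$region %in% c("left", "right"), ]
  rows <- lapply(seq_len(nrow(lobes)), function(i) {
    x <- lobes$pct_non[i] / 100
    expected <- 8 * x / (x + half_sat)
    raw <- stats::rnorm(n_fields, expected, noise_sd)
    data.frame(subject_id = lobes$subject_id[i], lobe = lobes$region[i],
               field_index = seq_len(n_fields),
               score = pmin(8L, pmax(0L, as.integer(round(raw)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
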