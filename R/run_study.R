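#' Build a validated run configuration
#'
#' A run is fully described by its configuration plus seed; persisting the
#' two makes the run reproducible. Configurations can also be loaded from
#' YAML via \code{\link{read_run_config}}.
#'
#' @param out_dir output directory for the report bundle.
#' @param manifest optional study manifest CSV path; when absent a
#'   synthetic phantom cohort is generated instead.
#' @param ashcroft optional per-field Ashcroft score CSV; when absent and
#'   the run is phantom-backed, synthetic scores are derived from the
#'   phantom ground truth.
#' @param design cohort design for phantom-backed runs (default
#'   \code{\link{default_cohort_design}}).
#' @param shape phantom array extents.
#' @param ranges an \code{\link{aeration_ranges}}.
#' @param compartment_phase phase for the aeration compartments
#'   (\code{"P02"} default).
#' @param normalize normalize biomarkers to the control mean (default
#'   TRUE).
#' @param inhibition_convention percent-change convention, see
#'   \code{\link{percent_change_vs_blm}}.
#' @param alpha significance level used in reports.
#' @param seed integer seed for every stochastic stage.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(out_dir, manifest = NULL, ashcroft = NULL,
                       design = default_cohort_design(),
                       shape = c(32L, 32L, 32L),
                       ranges = aeration_ranges(),
                       compartment_phase = "P02", normalize = TRUE,
                       inhibition_convention = "vs_blm", alpha = 0.05,
                       seed = 1L) {
  structure(list(out_dir = out_dir, manifest = manifest, ashcroft = ashcroft,
                 design = design, shape = as.integer(shape), ranges = ranges,
                 compartment_phase = compartment_phase, normalize = normalize,
                 inhibition_convention = inhibition_convention,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of
#'   \code{\link{run_config}} (\code{ranges} as a list of three length-2
#'   vectors \code{normo}/\code{hypo}/\code{non}; \code{design} as a list
#'   of row records).
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_fibroct("fibroct_io_error", sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- list(out_dir = y$out_dir %||% ".")
  for (key in c("manifest", "ashcroft", "compartment_phase", "normalize",
                "inhibition_convention", "alpha", "seed", "shape"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$ranges))
    args$ranges <- aeration_ranges(unlist(y$ranges$normo), unlist(y$ranges$hypo),
                                   unlist(y$ranges$non))
  if (!is.null(y$design))
    args$design <- do.call(rbind, lapply(y$design, as.data.frame))
  do.call(run_config, args)
}

# hash of the scientific configuration only: filesystem locations are
# excluded so equal parameterizations hash equally wherever they run
config_hash <- function(config) {
  sci <- unclass(config)
  sci$out_dir <- NULL
  fnv1a32(jsonlite::toJSON(sci, auto_unbox = TRUE, digits = NA, force = TRUE))
}

write_report_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full quantification study
#'
#' Orchestrates the pipeline end to end: phantom generation (or manifest
#' loading), per-lobe biomarker extraction, control normalization,
#' longitudinal ANOVA with post-hoc contrasts, percent
#' inhibition/recovery at day 21, paired left/right lobe significance
#' matrix, Ashcroft aggregation and Spearman correlation. All tables are
#' written to the configured output directory as CSV with the
#' configuration hash in a comment header, plus a machine-readable run
#' manifest (\code{run_manifest.json}). Runs are deterministic for equal
#' configurations.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with every computed table and the bundle
#'   paths.
#' @export
run_study <- function(config) {
  if (!inherits(config, "run_config"))
    stop_fibroct("fibroct_validation_error", "`config` must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  truths <- NULL
  if (!is.null(config$manifest)) {
    man <- read_manifest(config$manifest)
    biomk <- compute_biomarkers(man, ranges = config$ranges,
                                compartment_phase = config$compartment_phase)
  } else {
    cohort <- generate_cohort(config$design, seed = config$seed,
                              shape = config$shape)
    pairs <- lapply(cohort$subjects, function(s) s$pair)
    for (i in seq_along(pairs))
      attr(pairs[[i]], "group") <- cohort$manifest$group[i]
    biomk <- compute_biomarkers(pairs, ranges = config$ranges,
                                compartment_phase = config$compartment_phase)
    truths <- do.call(rbind, lapply(cohort$subjects, function(s) s$truth$biomarkers))
  }

  study <- as_study_table(biomk)
  study_norm <- if (config$normalize) normalize_to_control(study) else study

  biomarkers_tested <- unique(study$biomarker)
  eff_rows <- list()
  for (bm in biomarkers_tested) {
    for (rg in c("whole", "left", "right")) {
      es <- suppressWarnings(longitudinal_tests(study_norm, bm, rg))
      pc <- try(percent_change_vs_blm(study_norm, bm, rg,
                                      convention = config$inhibition_convention),
                silent = TRUE)
      pct <- if (inherits(pc, "try-error")) NA_real_ else pc$percent
      lbl <- if (inherits(pc, "try-error")) NA_character_ else pc$label
      for (i in seq_len(nrow(es$between))) {
        b <- es$between[i, ]
        eff_rows[[length(eff_rows) + 1L]] <- data.frame(
          biomarker = bm, region = rg, type = "between", day = b$day,
          contrast = b$contrast, estimate = b$estimate, p_raw = b$p_raw,
          p_adjusted = b$p_dunnett, adjustment = "dunnett",
          percent_change_day21 = pct, change_label = lbl)
      }
      if (!is.null(es$within)) for (i in seq_len(nrow(es$within))) {
        w <- es$within[i, ]
        eff_rows[[length(eff_rows) + 1L]] <- data.frame(
          biomarker = bm, region = rg, type = "within", day = NA_real_,
          contrast = sprintf("%s: day21 - day7", w$group), estimate = w$estimate,
          p_raw = w$p_raw, p_adjusted = w$p_sidak, adjustment = "sidak",
          percent_change_day21 = pct, change_label = lbl)
      }
    }
  }
  effects <- do.call(rbind, eff_rows)

  lobe_sig <- lobe_significance_matrix(study_norm)

  # histology: real scores if provided, synthetic from ground truth otherwise
  ash <- NULL; ash_sum <- NULL; spear <- NULL
  if (!is.null(config$ashcroft)) {
    ash <- read_ashcroft(config$ashcroft)
  } else if (!is.null(truths)) {
    day21 <- truths[truths$day == 21, ]
    ash <- synthetic_ashcroft(day21, seed = derive_seed(config$seed, "ashcroft"))
  }
  if (!is.null(ash)) {
    ash_sum <- ashcroft_table(ash)
    spear <- do.call(rbind, lapply(c("whole", "left", "right"), function(rg)
      spearman_matrix(study, ash_sum, region = rg, alpha = config$alpha)))
  }

  paths <- c(
    biomarkers = write_report_csv(biomk, file.path(config$out_dir, "biomarkers.csv"), hash),
    study = write_report_csv(study_norm, file.path(config$out_dir, "study_table.csv"), hash),
    effects = write_report_csv(effects, file.path(config$out_dir, "effect_summary.csv"), hash),
    lobe_sig = write_report_csv(lobe_sig, file.path(config$out_dir, "lobe_significance.csv"), hash)
  )
  if (!is.null(ash_sum)) {
    paths["ashcroft"] <- write_report_csv(ash_sum, file.path(config$out_dir, "ashcroft_summary.csv"), hash)
    paths["spearman"] <- write_report_csv(spear, file.path(config$out_dir, "spearman.csv"), hash)
  }
  run_manifest <- list(config_hash = hash, seed = config$seed,
                       package_version = as.character(utils::packageVersion("fibroct")),
                       n_records = nrow(biomk),
                       files = as.list(basename(paths)))
  jsonlite::write_json(run_manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(biomarkers = biomk, study = study, study_normalized = study_norm,
                 effects = effects, lobe_significance = lobe_sig,
                 ashcroft = ash_sum, spearman = spear, truths = truths,
                 config_hash = hash, paths = paths))
}

#' One-command synthetic demo run
#'
#' Generates a small phantom cohort (default group sizes 4/7/12 over days
#' 7, 14, 21 at 32-cubed voxels) and runs the whole pipeline on it. Two
#' runs with the same seed produce bit-identical output tables.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param shape phantom extents (default \code{c(32,32,32)}).
#' @param design cohort design (default
#'   \code{\link{default_cohort_design}}).
#' @return Invisibly, the \code{\link{run_study}} result list.
#' @export
run_demo <- function(out_dir, seed = 1L, shape = c(32L, 32L, 32L),
                     design = default_cohort_design()) {
  cfg <- run_config(out_dir = out_dir, design = design, shape = shape,
                    seed = seed)
  run_study(cfg)
}
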