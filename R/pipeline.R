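# End-to-end orchestration: schema validation of the long-format input
# tables, one-call execution of qc -> normalize -> paired -> unpaired ->
# interpretation, and CSV/report output. A single long-format schema serves
# both synthetic and real study tables, so the real data could be dropped in
# unchanged.

.pm_sample_cols <- c("sample_id", "case_id", "timepoint_label",
                     "sample_type", "batch_id", "time_since_death_h")

#' Validate a long-format study table
#'
#' Checks a combined long table (columns `sample_id, case_id,
#' timepoint_label, sample_type, batch_id, time_since_death_h, analyte,
#' peak_area`) against the input contract: required columns present, peak
#' areas positive, study samples carrying a time since death, every study
#' case having exactly one t1 and one t2 sample, and every batch providing
#' pool records. Violations are reported, not thrown.
#'
#' @param x Data frame or path to a CSV file.
#' @return Tibble of violations (`check`, `detail`); zero rows means clean.
#' @export
validate_table <- function(x) {
  if (is.character(x)) x <- read.csv(x, stringsAsFactors = FALSE)
  v <- list()
  note <- function(check, detail) {
    v[[length(v) + 1L]] <<- tibble(check = check, detail = detail)
  }
  need <- c(.pm_sample_cols, "analyte", "peak_area")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    for (col in missing_cols) note("missing_column", col)
    return(do.call(rbind, v))
  }
  bad_area <- !is.finite(x$peak_area) | x$peak_area <= 0
  if (any(bad_area)) {
    note("nonpositive_area",
         paste0(sum(bad_area), " row(s), e.g. sample ",
                x$sample_id[which(bad_area)[1L]]))
  }
  study <- x$sample_type == "study"
  if (any(study & is.na(x$time_since_death_h))) {
    note("missing_time_since_death",
         paste(unique(x$sample_id[study & is.na(x$time_since_death_h)])[1L]))
  }
  s <- unique(x[study, c("sample_id", "case_id", "timepoint_label")])
  for (tp in c("t1", "t2")) {
    cnt <- table(s$case_id[s$timepoint_label == tp])
    all_cases <- unique(s$case_id)
    zero <- setdiff(all_cases, names(cnt))
    multi <- names(cnt)[cnt > 1L]
    if (length(zero) > 0L) {
      note("missing_timepoint", paste0("case ", zero[1L], " has no ", tp,
                                       " (", length(zero), " case(s))"))
    }
    if (length(multi) > 0L) {
      note("duplicate_timepoint", paste0("case ", multi[1L], " has ",
                                         cnt[multi[1L]], " ", tp, " rows"))
    }
  }
  batches <- unique(x$batch_id[study])
  pool_batches <- unique(x$batch_id[x$sample_type == "pool"])
  no_pool <- setdiff(batches, pool_batches)
  if (length(no_pool) > 0L) {
    note("batch_without_pool", paste(no_pool, collapse = ", "))
  }
  if (length(v) == 0L) {
    tibble(check = character(), detail = character())
  } else {
    do.call(rbind, v)
  }
}

#' Write a cohort to CSV files
#'
#' Emits the long-format area table (joined with the sample metadata), the
#' IS areas, the pair table, the ground-truth sidecar and the configuration
#' (YAML) into a directory.
#'
#' @param cohort A `pm_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- cohort$samples[match(cohort$areas$sample_id,
                               cohort$samples$sample_id), ]
  long <- cbind(info[.pm_sample_cols],
                cohort$areas[c("analyte", "area")])
  names(long)[names(long) == "area"] <- "peak_area"
  paths <- c(
    areas = file.path(dir, "areas.csv"),
    is_areas = file.path(dir, "is_areas.csv"),
    pairs = file.path(dir, "pairs.csv"),
    truth = file.path(dir, "ground_truth.csv"),
    config = file.path(dir, "config.yaml")
  )
  write.csv(long, paths["areas"], row.names = FALSE)
  write.csv(cohort$is_areas, paths["is_areas"], row.names = FALSE)
  write.csv(cohort$pairs, paths["pairs"], row.names = FALSE)
  write.csv(cohort$truth$analytes, paths["truth"], row.names = FALSE)
  cfg <- cohort$config
  cfg_list <- unclass(cfg)
  cfg_list$seed <- if (is.null(cfg$seed)) "none" else cfg$seed
  yaml::write_yaml(cfg_list, paths["config"])
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on a cohort: table validation, quality
#' control, normalization, the paired stage (on raw areas, following the
#' study; batch factors cancel within a case), the unpaired stage (on
#' batch-corrected areas), pattern classification, physicochemical
#' correlations and the paired/unpaired concordance, and writes every stage
#' output plus a summary report to `out_dir`. Deterministic given the
#' cohort (generation itself is seeded via [cohort_config()]).
#'
#' @param cohort A `pm_cohort` from [generate_cohort()] (or an equivalent
#'   list built from real tables).
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output.
#' @param panel Panel tibble for the correlation stage (default
#'   [pm_panel()]; set `NULL` to skip correlations).
#' @param normalization Mode for the unpaired stage: `"batch_only"` (the
#'   study's final choice), `"is"` or `"pqn"`.
#' @param alpha Significance level.
#' @return Object of class `pm_pipeline_result`: list with `qc`,
#'   `paired_summary`, `unpaired`, `sampling_check`, `patterns`,
#'   `correlations`, `concordance`, `validation` and `paths`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, panel = pm_panel(),
                         normalization = c("batch_only", "is", "pqn"),
                         alpha = 0.05) {
  normalization <- match.arg(normalization)
  info <- cohort$samples[match(cohort$areas$sample_id,
                               cohort$samples$sample_id), ]
  long <- cbind(info[.pm_sample_cols], cohort$areas[c("analyte", "area")])
  names(long)[names(long) == "area"] <- "peak_area"
  validation <- validate_table(long)
  if (nrow(validation) > 0L &&
      any(validation$check %in% c("missing_column", "nonpositive_area"))) {
    stop("input tables violate the schema:\n",
         paste(validation$check, validation$detail, sep = ": ",
               collapse = "\n"), call. = FALSE)
  }

  qc <- qc_report(cohort, alpha = alpha)

  normalized <- switch(normalization,
    batch_only = batch_correct(cohort$areas, cohort$samples),
    is = is_normalize(cohort$areas, cohort$is_areas),
    pqn = pqn_normalize(batch_correct(cohort$areas, cohort$samples),
                        cohort$samples)
  )

  paired_summary <- run_paired_stage(cohort$areas, cohort$pairs,
                                     alpha = alpha)
  unpaired <- run_unpaired_stage(normalized, cohort$samples, alpha = alpha)
  sampling_check <- tryCatch(
    compare_sampling_procedures(normalized, cohort$samples),
    error = function(e) {
      message("sampling-procedure check skipped: ", conditionMessage(e))
      NULL
    }
  )
  patterns <- classify_patterns(paired_summary)
  concordance <- paired_unpaired_concordance(paired_summary, unpaired)

  correlations <- NULL
  if (!is.null(panel)) {
    overall <- paired_summary[paired_summary$bin == "all", ]
    changes <- tibble(analyte = overall$analyte, change = overall$median_pct)
    correlations <- do.call(rbind, lapply(
      c("logp", "mw", "rt_rp_min", "rt_hilic_min"),
      function(p) {
        tryCatch(correlate_properties(changes, panel, p),
                 error = function(e) NULL)
      }
    ))
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(out_dir, name)
    write.csv(qc$is_rsd, out("qc_is_rsd.csv"), row.names = FALSE)
    write.csv(qc$pool_rsd, out("qc_pool_rsd.csv"), row.names = FALSE)
    write.csv(qc$outliers$tests, out("qc_is_outliers.csv"),
              row.names = FALSE)
    write.csv(qc$drift$area, out("qc_pool_drift.csv"), row.names = FALSE)
    norm_out <- cbind(normalized,
                      mode = rep(norm_mode(normalized), nrow(normalized)))
    write.csv(norm_out, out("normalized_areas.csv"), row.names = FALSE)
    if (!is.null(pqn_factors(normalized))) {
      write.csv(pqn_factors(normalized), out("pqn_factors.csv"),
                row.names = FALSE)
    }
    write.csv(paired_summary, out("paired_summary.csv"), row.names = FALSE)
    write.csv(unpaired$groups, out("unpaired_groups.csv"),
              row.names = FALSE)
    write.csv(unpaired$kw, out("unpaired_kw.csv"), row.names = FALSE)
    write.csv(unpaired$dunn, out("unpaired_dunn.csv"), row.names = FALSE)
    if (!is.null(sampling_check)) {
      write.csv(sampling_check, out("sampling_check.csv"),
                row.names = FALSE)
    }
    write.csv(patterns, out("patterns.csv"), row.names = FALSE)
    if (!is.null(correlations)) {
      write.csv(correlations, out("correlations.csv"), row.names = FALSE)
    }
    write.csv(concordance$data, out("concordance.csv"), row.names = FALSE)
    .pm_write_report(out("report.md"), cohort, qc, paired_summary, unpaired,
                     patterns, correlations, concordance, normalization,
                     alpha)
    cfg <- unclass(cohort$config)
    cfg$seed <- if (is.null(cfg$seed)) "none" else cfg$seed
    cfg$normalization <- normalization
    cfg$alpha <- alpha
    yaml::write_yaml(cfg, out("effective_config.yaml"))
    paths <- out(c("paired_summary.csv", "unpaired_groups.csv",
                   "patterns.csv", "report.md"))
  }

  structure(
    list(qc = qc, normalized = normalized, paired_summary = paired_summary,
         unpaired = unpaired, sampling_check = sampling_check,
         patterns = patterns, correlations = correlations,
         concordance = concordance, validation = validation,
         normalization = normalization, paths = paths),
    class = "pm_pipeline_result"
  )
}

.pm_write_report <- function(path, cohort, qc, paired_summary, unpaired,
                             patterns, correlations, concordance,
                             normalization, alpha) {
  overall <- paired_summary[paired_summary$bin == "all", ]
  n_sig <- sum(overall$p_adj < alpha, na.rm = TRUE)
  kw_sig <- sum(unpaired$kw$p_adj < alpha, na.rm = TRUE)
  lines <- c(
    "# Postmortem time-dependence report",
    "",
    sprintf("- cases: %d; samples: %d (of which %d pools); analytes: %d",
            nrow(cohort$pairs), nrow(cohort$samples),
            sum(cohort$samples$sample_type == "pool"),
            length(unique(cohort$areas$analyte))),
    sprintf("- seed: %s; unpaired normalization: %s; alpha = %g",
            if (is.null(cohort$config$seed)) "none" else cohort$config$seed,
            normalization, alpha),
    sprintf("- median t1 = %.1f h; median Dt = %.1f h",
            median(cohort$pairs$t1_h), median(cohort$pairs$delta_t_h)),
    "",
    "## Quality control",
    sprintf("- overall QC pass: %s; samples excluded by the all-IS rule: %d",
            qc$pass, length(qc$outliers$excluded_samples)),
    "",
    "## Paired analysis (t2 vs t1)",
    sprintf("- %d of %d analytes with Holm-adjusted p < %g overall",
            n_sig, nrow(overall), alpha),
    "",
    "## Unpaired analysis (time since death)",
    sprintf("- %d of %d analytes Kruskal-Wallis significant (Holm)",
            kw_sig, nrow(unpaired$kw)),
    sprintf("- cases with t1 and t2 in the same time group: %d (of which %d sampled > 144 h)",
            unpaired$same_group_cases$n,
            unpaired$same_group_cases$n_over_144h),
    "",
    "## Interpretation",
    sprintf("- temporal patterns: %s",
            paste(sprintf("%s = %d", names(table(patterns$pattern)),
                          as.integer(table(patterns$pattern))),
                  collapse = ", ")),
    sprintf("- paired/unpaired concordance: Spearman rho^2 = %.3f (n = %d)",
            concordance$rho_sq, concordance$n)
  )
  if (!is.null(correlations)) {
    lines <- c(lines, "",
               "## Property correlations (overall paired change)",
               sprintf("- %s: rho = %.3f (p = %.3g, n = %d)",
                       correlations$property, correlations$rho,
                       correlations$p_value, correlations$n))
  }
  writeLines(lines, path)
  invisible(path)
}
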