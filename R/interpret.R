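# Interpretation stage: four-pattern temporal classification of the per-bin
# median change profiles, correlation of change magnitude with
# physicochemical properties, paired/unpaired concordance, side-by-side
# comparison of normalization modes, and cross-platform (RP vs HILIC) trend
# concordance.

#' Classify a temporal median-change profile into one of four patterns
#'
#' Rule-based reconstruction of the study's four-pattern taxonomy, applied
#' to per-bin median percent changes (ordered by increasing interval):
#'
#' 1. `stable` - every median stays within the `stable_band` (the study's
#'    "no or < 30% change over time").
#' 2. `decrease` - the final median falls at or below `-stable_band` and no
#'    bin exceeds `+stable_band`.
#' 3. `lag_then_increase` - all bins covering up to `lag_limit_h` stay
#'    within the band, the profile is still flat at the end of the lag
#'    window (last early median below half the band, so a steady rise that
#'    merely has not crossed the band yet does not count as a lag), and a
#'    later bin exceeds `+stable_band`.
#' 4. `steady_increase` - the first out-of-band bin is positive and the
#'    final value is the profile's running maximum within a 10% tolerance.
#'
#' Profiles matching none of the rules fall back to the nearest rule by
#' their final median, flagged with low confidence (the study assigns every
#' compound to one of the four groups).
#'
#' @param medians Per-bin median percent changes (ordered; `NA` = empty
#'   bin, dropped together with its edge).
#' @param upper_edges_h Upper bin edges in hours, same length as `medians`
#'   (default: the paired Dt scheme's edges).
#' @param stable_band Band in percent (default 30).
#' @param lag_limit_h End of the lag window in hours (default 36).
#' @return List with `pattern`, `confidence` (`"high"`/`"low"`) and
#'   `evidence` (the populated medians used).
#' @export
#' @examples
#' classify_pattern(c(5, 10, 25, 60, 120, 160),
#'                  upper_edges_h = c(12, 24, 36, 48, 72, 96))
classify_pattern <- function(medians,
                             upper_edges_h = bin_scheme("paired_dt")$edges[-1],
                             stable_band = 30, lag_limit_h = 36) {
  if (length(medians) != length(upper_edges_h)) {
    stop("`medians` and `upper_edges_h` must have equal length",
         call. = FALSE)
  }
  keep <- !is.na(medians)
  m <- medians[keep]
  e <- upper_edges_h[keep]
  if (length(m) < 4L) {
    stop("need at least 4 populated bins to classify", call. = FALSE)
  }
  res <- function(pattern, confidence) {
    list(pattern = pattern, confidence = confidence,
         evidence = setNames(m, paste0("<=", e, "h")))
  }
  last <- m[length(m)]
  if (all(abs(m) < stable_band)) return(res("stable", "high"))
  if (last <= -stable_band && all(m <= stable_band)) {
    return(res("decrease", "high"))
  }
  early <- m[e <= lag_limit_h]
  later <- m[e > lag_limit_h]
  if (length(early) > 0L && all(abs(early) < stable_band) &&
      early[length(early)] < stable_band / 2 &&
      any(later > stable_band)) {
    return(res("lag_then_increase", "high"))
  }
  out_of_band <- which(abs(m) >= stable_band)
  if (length(out_of_band) > 0L && m[out_of_band[1L]] > 0 &&
      last >= max(m) - 0.1 * max(abs(m))) {
    return(res("steady_increase", "high"))
  }
  # fall-back: nearest rule by the final median, low confidence
  if (last > stable_band) return(res("steady_increase", "low"))
  if (last < -stable_band) return(res("decrease", "low"))
  res("stable", "low")
}

#' Classify every analyte of a paired summary
#'
#' Applies [classify_pattern()] to the per-bin rows of a
#' [run_paired_stage()] summary.
#'
#' @param paired_summary Output of [run_paired_stage()] (with bins).
#' @param scheme The Dt scheme used (default `bin_scheme("paired_dt")`).
#' @param ... Passed to [classify_pattern()].
#' @return Tibble `analyte, pattern, confidence`.
#' @export
classify_patterns <- function(paired_summary,
                              scheme = bin_scheme("paired_dt"), ...) {
  binned <- paired_summary[paired_summary$bin != "all", ]
  out <- lapply(split(binned, binned$analyte), function(sub) {
    sub <- sub[match(scheme$labels, sub$bin), ]
    med <- ifelse(sub$n_pairs > 0L, sub$median_pct, NA_real_)
    cl <- classify_pattern(med, upper_edges_h = scheme$edges[-1], ...)
    tibble(analyte = sub$analyte[1L], pattern = cl$pattern,
           confidence = cl$confidence)
  })
  out <- do.call(rbind, out)
  out[match(unique(binned$analyte), out$analyte), ]
}

#' Correlate per-analyte change with a physicochemical property
#'
#' Spearman correlation between a per-analyte change measure (e.g. the
#' overall paired median percent change) and a panel property (logP,
#' molecular weight or retention time). Analytes lacking the property are
#' excluded and counted.
#'
#' @param changes Tibble `analyte, change`.
#' @param panel Panel tibble (see [pm_panel()]).
#' @param property One of `"logp"`, `"mw"`, `"rt_rp_min"`, `"rt_hilic_min"`.
#' @return Tibble with `property, rho, rho_sq, p_value, n, n_excluded`.
#' @export
correlate_properties <- function(changes, panel,
                                 property = c("logp", "mw", "rt_rp_min",
                                              "rt_hilic_min")) {
  property <- match.arg(property)
  prop <- panel[[property]][match(changes$analyte, panel$name)]
  keep <- !is.na(prop) & !is.na(changes$change)
  if (sum(keep) < 3L) {
    stop("fewer than 3 analytes with both change and ", property,
         call. = FALSE)
  }
  sp <- spearman_rank(changes$change[keep], prop[keep])
  tibble(property = property, rho = sp$rho, rho_sq = sp$rho_sq,
         p_value = sp$p_value, n = sp$n, n_excluded = sum(!keep))
}

#' Concordance between paired and unpaired change estimates
#'
#' Spearman correlation, per analyte, of the overall paired median percent
#' change (t2 vs t1) against the highest unpaired percent change vs time
#' group 1 - the study's check that both evaluation strategies agree.
#'
#' @param paired_summary Output of [run_paired_stage()].
#' @param unpaired Output of [run_unpaired_stage()] (or its `groups`).
#' @return List with `rho`, `rho_sq`, `p_value`, `n` and the per-analyte
#'   `data` tibble (`analyte, paired_pct, unpaired_pct`).
#' @export
paired_unpaired_concordance <- function(paired_summary, unpaired) {
  overall <- paired_summary[paired_summary$bin == "all", ]
  hc <- highest_change(unpaired)
  only_paired <- setdiff(overall$analyte, hc$analyte)
  only_unpaired <- setdiff(hc$analyte, overall$analyte)
  if (length(only_paired) > 0L || length(only_unpaired) > 0L) {
    stop("analyte sets differ between the two summaries; only paired: ",
         paste(only_paired, collapse = ", "), "; only unpaired: ",
         paste(only_unpaired, collapse = ", "), call. = FALSE)
  }
  dat <- tibble(
    analyte = overall$analyte,
    paired_pct = overall$median_pct,
    unpaired_pct = hc$highest_pct[match(overall$analyte, hc$analyte)]
  )
  sp <- spearman_rank(dat$paired_pct, dat$unpaired_pct)
  list(rho = sp$rho, rho_sq = sp$rho_sq, p_value = sp$p_value, n = sp$n,
       data = dat)
}

#' Run both stages under several normalization modes
#'
#' Normalizes a cohort under each requested mode (pooled-QC batch correction
#' only; internal-standard normalization; PQN layered on batch-corrected
#' data), runs the paired and unpaired stages on each normalized table, and
#' reports the PQN attenuation: the ratio of the PQN-mode to the
#' batch-only-mode absolute overall median change for drifted analytes.
#' When many analytes carry a real temporal drift, PQN partly attributes it
#' to dilution and the ratio drops below 1.
#'
#' @param cohort A `pm_cohort`.
#' @param modes Subset of `c("batch_only", "is", "pqn")`.
#' @param drifted Analytes counted as drifted for the attenuation statistic
#'   (default: cohort ground-truth analytes with a non-stable pattern).
#' @param run_unpaired Also run the unpaired stage per mode (default TRUE).
#' @param pqn_reference Passed to [pqn_normalize()].
#' @return List with `paired` (named list of paired summaries), `unpaired`
#'   (named list or NULL), and `attenuation` (`ratios` tibble and
#'   `median_ratio`).
#' @export
compare_normalization_modes <- function(cohort,
                                        modes = c("batch_only", "is", "pqn"),
                                        drifted = NULL,
                                        run_unpaired = TRUE,
                                        pqn_reference = "pool_mean") {
  modes <- match.arg(modes, c("batch_only", "is", "pqn"), several.ok = TRUE)
  norm_tables <- list()
  for (mode in modes) {
    tab <- tryCatch(switch(mode,
      batch_only = batch_correct(cohort$areas, cohort$samples),
      is = is_normalize(cohort$areas, cohort$is_areas),
      pqn = pqn_normalize(batch_correct(cohort$areas, cohort$samples),
                          cohort$samples, reference = pqn_reference)
    ), error = function(e) {
      message("mode '", mode, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(tab)) norm_tables[[mode]] <- tab
  }
  paired <- lapply(norm_tables, function(tab) {
    run_paired_stage(tab, cohort$pairs, bins = FALSE)
  })
  unpaired <- if (run_unpaired) {
    lapply(norm_tables, function(tab) run_unpaired_stage(tab, cohort$samples))
  } else NULL

  attenuation <- NULL
  if (all(c("batch_only", "pqn") %in% names(paired))) {
    if (is.null(drifted)) {
      drifted <- cohort$truth$analytes$analyte[
        cohort$truth$analytes$pattern != "stable"]
    }
    b <- paired$batch_only[paired$batch_only$bin == "all", ]
    q <- paired$pqn[paired$pqn$bin == "all", ]
    keep <- b$analyte %in% drifted & abs(b$median_pct) > 0
    ratios <- tibble(
      analyte = b$analyte[keep],
      batch_only_pct = b$median_pct[keep],
      pqn_pct = q$median_pct[match(b$analyte[keep], q$analyte)],
      ratio = abs(q$median_pct[match(b$analyte[keep], q$analyte)]) /
        abs(b$median_pct[keep])
    )
    attenuation <- list(ratios = ratios,
                        median_ratio = median(ratios$ratio))
  }
  list(paired = paired, unpaired = unpaired, attenuation = attenuation)
}

#' Cross-platform trend concordance (e.g. RP vs HILIC)
#'
#' Per analyte, Spearman correlation between the per-bin median-change
#' profiles obtained under two chromatography modes; analytes whose profiles
#' anti-correlate (rho < 0) are listed as discordant (the study found
#' proline and valine discordant between RP and HILIC).
#'
#' @param summary_a,summary_b Two [run_paired_stage()] summaries on the
#'   same bin scheme.
#' @param min_bins Minimum shared populated bins per analyte (default 3).
#' @return Tibble `analyte, rho, n_bins, discordant`.
#' @export
cross_platform_concordance <- function(summary_a, summary_b, min_bins = 3L) {
  a <- summary_a[summary_a$bin != "all" & summary_a$n_pairs > 0L, ]
  b <- summary_b[summary_b$bin != "all" & summary_b$n_pairs > 0L, ]
  shared <- intersect(unique(a$analyte), unique(b$analyte))
  if (length(shared) == 0L) {
    stop("no overlapping analytes between the two summaries", call. = FALSE)
  }
  rows <- list()
  for (an in shared) {
    sa <- a[a$analyte == an, ]
    sb <- b[b$analyte == an, ]
    common <- intersect(sa$bin, sb$bin)
    if (length(common) < min_bins) next
    va <- sa$median_pct[match(common, sa$bin)]
    vb <- sb$median_pct[match(common, sb$bin)]
    sp <- tryCatch(spearman_rank(va, vb), error = function(e) NULL)
    if (is.null(sp)) next
    rows[[length(rows) + 1L]] <- tibble(
      analyte = an, rho = sp$rho, n_bins = length(common),
      discordant = sp$rho < 0
    )
  }
  if (length(rows) == 0L) {
    stop("no analyte had at least ", min_bins, " shared populated bins",
         call. = FALSE)
  }
  do.call(rbind, rows)
}
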