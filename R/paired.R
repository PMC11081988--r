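# Paired analysis: per-case percent change between the autopsy (t2) and
# admission (t1) samples of the same case, computed on raw peak areas (the
# two samples of a case are measured in the same batch, so batch factors
# cancel in the ratio), binned by the collection interval Dt, with a paired
# Wilcoxon signed-rank test overall and per Dt bin and Holm adjustment
# across analytes within each comparison family.

#' Percent change between paired areas
#'
#' `100 * (t2 - t1) / t1`.
#'
#' @param area_t1,area_t2 Positive numeric vectors (recycled pairwise).
#' @return Percent change vector.
#' @export
#' @examples
#' percent_change(100, 250)  # +150
percent_change <- function(area_t1, area_t2) {
  if (any(area_t1 <= 0, na.rm = TRUE)) {
    stop("t1 areas must be positive", call. = FALSE)
  }
  100 * (area_t2 - area_t1) / area_t1
}

#' Per-case, per-analyte paired changes
#'
#' Joins the area table onto the case pairs and computes the percent change
#' for every (case, analyte). Pairs with a non-positive or missing t1 area
#' are skipped and counted (attribute `n_skipped`).
#'
#' @param areas Long area table (raw areas by default, following the study;
#'   pass a normalized table to compare normalization modes).
#' @param pairs Pair table (`case_id`, `sample_id_t1`, `sample_id_t2`,
#'   `delta_t_h`).
#' @return Tibble `case_id, analyte, delta_t_h, area_t1, area_t2,
#'   pct_change`.
#' @export
pair_changes <- function(areas, pairs) {
  analytes <- unique(areas$analyte)
  key <- paste(areas$sample_id, areas$analyte, sep = "\r")
  n_p <- nrow(pairs); n_a <- length(analytes)
  long_case <- rep(pairs$case_id, times = n_a)
  long_analyte <- rep(analytes, each = n_p)
  a1 <- areas$area[match(paste(rep(pairs$sample_id_t1, times = n_a),
                               long_analyte, sep = "\r"), key)]
  a2 <- areas$area[match(paste(rep(pairs$sample_id_t2, times = n_a),
                               long_analyte, sep = "\r"), key)]
  usable <- !is.na(a1) & !is.na(a2) & a1 > 0
  n_skipped <- sum(!usable)
  out <- tibble(
    case_id = long_case[usable],
    analyte = long_analyte[usable],
    delta_t_h = rep(pairs$delta_t_h, times = n_a)[usable],
    area_t1 = a1[usable],
    area_t2 = a2[usable],
    pct_change = 100 * (a2[usable] - a1[usable]) / a1[usable]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Paired-analysis stage
#'
#' For every analyte: median percent change with a distribution-free 95%
#' confidence interval and a paired Wilcoxon signed-rank test between t2 and
#' t1 areas, overall (`bin = "all"`) and within each Dt bin of `scheme`.
#' P-values are Holm-adjusted across analytes separately within each family
#' (the overall comparison and each bin form their own family).
#'
#' @param areas Long area table (raw areas per the study design).
#' @param pairs Pair table as in [pair_changes()].
#' @param scheme Dt bin scheme (default `bin_scheme("paired_dt")`).
#' @param alpha Significance level for the code column.
#' @param exact_max_n Passed to [wilcoxon_signed_rank()].
#' @param bins If `FALSE`, only the overall (`"all"`) family is computed.
#' @param tests If `FALSE`, skips the signed-rank tests (medians and CIs
#'   only; used for fast pattern classification).
#' @param ci_level Confidence level of the median interval.
#' @return Tibble `analyte, bin, n_pairs, median_pct, ci_low, ci_high,
#'   statistic, p_raw, p_adj, code`; rows with `n_pairs = 0` carry `NA`
#'   statistics. Attribute `n_skipped` counts pairs dropped for
#'   non-positive t1 areas.
#' @export
run_paired_stage <- function(areas, pairs, scheme = bin_scheme("paired_dt"),
                             alpha = 0.05, exact_max_n = 25L, bins = TRUE,
                             tests = TRUE, ci_level = 0.95) {
  if (nrow(pairs) < 1L) stop("need at least one pair", call. = FALSE)
  ct <- pair_changes(areas, pairs)
  analytes <- unique(areas$analyte)
  ct$bin <- assign_bin(ct$delta_t_h, scheme)
  families <- c("all", if (bins) scheme$labels)

  rows <- vector("list", length(families))
  for (fi in seq_along(families)) {
    fam <- families[fi]
    sub <- if (fam == "all") ct else ct[!is.na(ct$bin) & ct$bin == fam, ]
    by_a <- split(sub, factor(sub$analyte, levels = analytes))
    stat <- p_raw <- med <- lo <- hi <- rep(NA_real_, length(analytes))
    n_pairs <- integer(length(analytes))
    for (ai in seq_along(analytes)) {
      g <- by_a[[ai]]
      n_pairs[ai] <- nrow(g)
      if (n_pairs[ai] == 0L) next
      ci <- median_ci(g$pct_change, level = ci_level)
      med[ai] <- ci$median; lo[ai] <- ci$ci_low; hi[ai] <- ci$ci_high
      if (tests) {
        w <- wilcoxon_signed_rank(g$area_t2, g$area_t1,
                                  exact_max_n = exact_max_n)
        stat[ai] <- w$statistic
        p_raw[ai] <- w$p_value
      }
    }
    p_adj <- rep(NA_real_, length(analytes))
    idx <- !is.na(p_raw)
    if (any(idx)) p_adj[idx] <- holm_adjust(p_raw[idx])
    rows[[fi]] <- tibble(
      analyte = analytes, bin = fam, n_pairs = n_pairs,
      median_pct = med, ci_low = lo, ci_high = hi,
      statistic = stat, p_raw = p_raw, p_adj = p_adj,
      code = significance_code(p_adj)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "n_skipped") <- attr(ct, "n_skipped")
  attr(out, "scheme") <- scheme$name
  out
}
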