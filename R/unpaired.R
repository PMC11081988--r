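# Unpaired analysis: all individual samples (t1 and t2 of every case) are
# binned into groups by their time since death (tx_ToD) and compared per
# analyte with a Kruskal-Wallis test (Holm across analytes) followed by
# Dunn's post-hoc test on the Kruskal-Wallis-significant analytes (Holm
# across the group pairs). Consumes batch-corrected (normalized) areas,
# since samples of different cases sit in different batches.

#' Unpaired time-group stage
#'
#' @param areas Long **normalized** area table (batch-corrected at least).
#' @param samples Sample table with `sample_type`, `timepoint_label`,
#'   `case_id` and `time_since_death_h`.
#' @param scheme Time-since-death bin scheme (default
#'   `bin_scheme("unpaired_tod")`, the 10-group scheme).
#' @param alpha Gate for running Dunn's test on an analyte.
#' @param dunn_gate Whether the Dunn gate uses the Holm-adjusted (default)
#'   or raw Kruskal-Wallis p-value.
#' @return Object of class `pm_unpaired`: list with
#'   * `groups`: per (analyte, group): `n`, `median_area` and
#'     `pct_vs_group1` (percent difference of the group median to the
#'     group-1 median; 0 for group 1 itself),
#'   * `kw`: per analyte Kruskal-Wallis `statistic`, `df`, `p_raw`,
#'     `p_adj` (Holm across analytes), `code`,
#'   * `dunn`: tidy pairwise Dunn results (`analyte, group_i, group_j, z,
#'     p_raw, p_adj`) for gated analytes, Holm across the pairs per analyte,
#'   * `same_group_cases`: cases whose t1 and t2 fall into the same group
#'     (count plus how many of them were sampled later than 144 h),
#'   * `scheme`, `dropped_groups`.
#' @export
run_unpaired_stage <- function(areas, samples,
                               scheme = bin_scheme("unpaired_tod"),
                               alpha = 0.05,
                               dunn_gate = c("p_adj", "p_raw")) {
  dunn_gate <- match.arg(dunn_gate)
  info <- samples[match(areas$sample_id, samples$sample_id), ]
  study <- info$sample_type == "study"
  if (any(is.na(info$time_since_death_h[study]))) {
    stop("every study sample needs time_since_death_h", call. = FALSE)
  }
  dat <- tibble(
    sample_id = areas$sample_id[study],
    analyte = areas$analyte[study],
    value = areas$area[study],
    group = assign_bin(info$time_since_death_h[study], scheme)
  )
  present <- table(unique(dat[c("sample_id", "group")])$group) > 0
  dropped <- scheme$labels[!scheme$labels %in%
                             names(present)[present]]
  if (length(dropped) > 0L) {
    message("empty time group(s) dropped from testing: ",
            paste(dropped, collapse = ", "))
  }
  analytes <- unique(dat$analyte)

  group_rows <- list()
  kw_stat <- kw_p <- rep(NA_real_, length(analytes))
  kw_df <- rep(NA_integer_, length(analytes))
  for (ai in seq_along(analytes)) {
    sub <- dat[dat$analyte == analytes[ai], ]
    glist <- split(sub$value, sub$group)
    med <- vapply(glist, function(v) if (length(v)) median(v) else NA_real_,
                  numeric(1))
    n <- vapply(glist, length, integer(1))
    ref <- med[[scheme$labels[1L]]]
    pct <- if (!is.na(ref) && ref > 0) 100 * (med - ref) / ref else
      rep(NA_real_, length(med))
    pct[scheme$labels[1L]] <- if (!is.na(ref)) 0 else NA_real_
    group_rows[[ai]] <- tibble(
      analyte = analytes[ai], group = factor(names(med),
                                             levels = scheme$labels),
      n = n, median_area = med, pct_vs_group1 = as.numeric(pct)
    )
    nonempty <- glist[lengths(glist) > 0L]
    if (length(nonempty) >= 2L) {
      kw <- kruskal_wallis(nonempty)
      kw_stat[ai] <- kw$statistic
      kw_df[ai] <- kw$df
      kw_p[ai] <- kw$p_value
    }
  }
  kw_adj <- rep(NA_real_, length(analytes))
  ok <- !is.na(kw_p)
  if (any(ok)) kw_adj[ok] <- holm_adjust(kw_p[ok])
  kw <- tibble(analyte = analytes, statistic = kw_stat, df = kw_df,
               p_raw = kw_p, p_adj = kw_adj, code = significance_code(kw_adj))

  gate_p <- if (dunn_gate == "p_adj") kw$p_adj else kw$p_raw
  dunn_rows <- list()
  for (ai in which(!is.na(gate_p) & gate_p < alpha)) {
    sub <- dat[dat$analyte == analytes[ai], ]
    glist <- split(sub$value, sub$group)
    glist <- glist[lengths(glist) > 0L]
    dt <- dunns_test(glist, p_adjust = "holm")
    dt <- cbind(tibble(analyte = analytes[ai]), dt)
    dunn_rows[[length(dunn_rows) + 1L]] <- dt
  }
  dunn <- if (length(dunn_rows) > 0L) as_tibble(do.call(rbind, dunn_rows)) else
    tibble(analyte = character(), group_i = character(),
           group_j = character(), z = numeric(), p_raw = numeric(),
           p_adj = numeric())

  by_case <- info[study & !is.na(info$case_id), ]
  by_case <- unique(tibble(case_id = by_case$case_id,
                           timepoint = by_case$timepoint_label,
                           group = assign_bin(by_case$time_since_death_h,
                                              scheme),
                           t_h = by_case$time_since_death_h))
  t1g <- by_case[by_case$timepoint == "t1", ]
  t2g <- by_case[by_case$timepoint == "t2", ]
  m <- match(t1g$case_id, t2g$case_id)
  same <- !is.na(m) & t1g$group == t2g$group[m]
  same_ids <- t1g$case_id[same]
  over144 <- sum(t2g$t_h[m[same]] > 144, na.rm = TRUE)

  structure(
    list(groups = do.call(rbind, group_rows), kw = kw, dunn = dunn,
         same_group_cases = list(case_ids = same_ids,
                                 n = length(same_ids),
                                 n_over_144h = over144),
         scheme = scheme$name, dropped_groups = dropped),
    class = "pm_unpaired"
  )
}

#' Highest time-group change per analyte
#'
#' From the unpaired group profiles, picks per analyte the percent
#' difference to group 1 with the largest absolute value among groups 2..k
#' (ties broken toward the later group). All-zero profiles return 0% with
#' the earliest non-group-1 label and a `flat` flag.
#'
#' @param profiles A `pm_unpaired` object or its `groups` tibble.
#' @return Tibble `analyte, highest_pct, group, flat`.
#' @export
highest_change <- function(profiles) {
  groups <- if (inherits(profiles, "pm_unpaired")) profiles$groups else
    profiles
  out <- lapply(split(groups, groups$analyte), function(sub) {
    sub <- sub[order(as.integer(sub$group)), ]
    cand <- sub[-1L, ]
    cand <- cand[!is.na(cand$pct_vs_group1) & cand$n > 0L, ]
    if (nrow(cand) < 1L) {
      stop("need at least 2 populated groups for analyte ",
           sub$analyte[1L], call. = FALSE)
    }
    if (all(cand$pct_vs_group1 == 0)) {
      return(tibble(analyte = sub$analyte[1L], highest_pct = 0,
                    group = as.character(cand$group[1L]), flat = TRUE))
    }
    best <- max(abs(cand$pct_vs_group1))
    i <- max(which(abs(cand$pct_vs_group1) == best))  # later group on ties
    tibble(analyte = sub$analyte[1L], highest_pct = cand$pct_vs_group1[i],
           group = as.character(cand$group[i]), flat = FALSE)
  })
  out <- do.call(rbind, out)
  out[match(unique(groups$analyte), out$analyte), ]
}

#' Compare the two sampling procedures within one time group
#'
#' Within one time-since-death bin, compares t1-labelled against t2-labelled
#' study samples per analyte with a two-sided Mann-Whitney test (Holm across
#' analytes), reporting the direction and percent difference of medians.
#' The study ran this check in the 24-36 h group, its best-balanced bin.
#'
#' @param areas Long normalized area table.
#' @param samples Sample table.
#' @param bin Bin label (default `"24-36 h"`).
#' @param scheme Bin scheme (default the 10-group unpaired scheme).
#' @return Tibble `analyte, n_t1, n_t2, statistic, p_raw, p_adj, code,
#'   median_diff_pct` (percent difference of the t2 median vs the t1
#'   median).
#' @export
compare_sampling_procedures <- function(areas, samples, bin = "24-36 h",
                                        scheme = bin_scheme("unpaired_tod")) {
  info <- samples[match(areas$sample_id, samples$sample_id), ]
  study <- info$sample_type == "study"
  grp <- assign_bin(ifelse(study, info$time_since_death_h, NA), scheme)
  sel <- study & !is.na(grp) & grp == bin
  if (!any(sel & info$timepoint_label == "t1") ||
      !any(sel & info$timepoint_label == "t2")) {
    stop("bin '", bin, "' lacks t1 or t2 samples", call. = FALSE)
  }
  analytes <- unique(areas$analyte)
  stat <- p_raw <- diff_pct <- rep(NA_real_, length(analytes))
  n1 <- n2 <- integer(length(analytes))
  for (ai in seq_along(analytes)) {
    rows <- sel & areas$analyte == analytes[ai]
    v1 <- areas$area[rows & info$timepoint_label == "t1"]
    v2 <- areas$area[rows & info$timepoint_label == "t2"]
    n1[ai] <- length(v1); n2[ai] <- length(v2)
    mw <- mann_whitney(v1, v2)
    stat[ai] <- mw$statistic
    p_raw[ai] <- mw$p_value
    diff_pct[ai] <- 100 * (median(v2) / median(v1) - 1)
  }
  p_adj <- holm_adjust(p_raw)
  tibble(analyte = analytes, n_t1 = n1, n_t2 = n2, statistic = stat,
         p_raw = p_raw, p_adj = p_adj, code = significance_code(p_adj),
         median_diff_pct = diff_pct)
}
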