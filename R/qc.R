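# Quality control: relative standard deviations, Grubbs outlier screening
# on batch-normalized internal-standard areas, and retention-time /
# peak-area drift gates on the pooled-QC injections.

#' Relative standard deviation (percent)
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation.
#'
#' @param values Numeric vector, length >= 2, positive mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(8, 10, 12))  # 20
rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be positive", call. = FALSE)
  100 * sd(values) / m
}

#' Grubbs test for a single outlier
#'
#' Two-sided single-outlier Grubbs test: `G = max|x - mean| / sd`, compared
#' against the critical value
#' `((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the upper
#' `alpha / (2n)` quantile of Student's t with `n - 2` degrees of freedom.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level (default 0.05).
#' @return List with `g` (statistic), `critical`, `outlier_index` (index of
#'   the most extreme value if `g > critical`, else `NA`) and `degenerate`
#'   (`TRUE` when all values are identical; no outlier is reported then).
#' @export
#' @examples
#' grubbs_test(c(9.9, 10, 10.1, 10, 14))
grubbs_test <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs at least 3 values", call. = FALSE)
  s <- sd(values)
  if (s == 0) {
    return(list(g = 0, critical = NA_real_, outlier_index = NA_integer_,
                degenerate = TRUE))
  }
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  critical <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  list(
    g = g, critical = critical,
    outlier_index = if (g > critical) which.max(dev) else NA_integer_,
    degenerate = FALSE
  )
}

# batch-normalized IS areas: each study sample's IS area divided by the
# batch's pool-mean area of that IS (same transform as the batch correction
# of analyte areas)
.pm_is_batch_normalized <- function(is_areas, samples) {
  info <- samples[match(is_areas$sample_id, samples$sample_id), ]
  pool_rows <- info$sample_type == "pool"
  key <- paste(info$batch_id, is_areas$is_name, sep = "\r")
  pool_mean <- tapply(is_areas$area[pool_rows], key[pool_rows], mean)
  norm <- is_areas$area / as.numeric(pool_mean[key])
  tibble(
    sample_id = is_areas$sample_id,
    is_name = is_areas$is_name,
    batch_id = info$batch_id,
    sample_type = info$sample_type,
    value = norm
  )
}

#' Screen study samples for internal-standard outliers
#'
#' Runs a single-pass (non-iterative) Grubbs test per internal standard on
#' batch-normalized IS peak areas of the study samples. A sample is flagged
#' per IS when it is that IS's significant Grubbs outlier; it is *excluded*
#' only when flagged for **all** internal standards (the study's rule -
#' samples suspicious on a single IS are reported but retained).
#'
#' @param samples Sample table (`sample_id`, `sample_type`, `batch_id`).
#' @param is_areas Long IS table (`sample_id`, `is_name`, `area`).
#' @param alpha Grubbs significance level (default 0.05).
#' @param scope `"pooled"` (default): one Grubbs test per IS over all
#'   batch-normalized study samples; `"per_batch"`: one test per IS within
#'   each batch.
#' @return List with `tests` (per IS/scope: g, critical, flagged sample),
#'   `flags` (tibble `sample_id`, `is_name`), `excluded_samples` (character
#'   vector) and `n_is`.
#' @export
screen_is_outliers <- function(samples, is_areas, alpha = 0.05,
                               scope = c("pooled", "per_batch")) {
  scope <- match.arg(scope)
  miss <- is.na(is_areas$area)
  if (any(miss)) {
    warning("missing IS area for sample(s) ",
            paste(unique(is_areas$sample_id[miss]), collapse = ", "),
            "; skipped for the affected IS", call. = FALSE)
    is_areas <- is_areas[!miss, ]
  }
  norm <- .pm_is_batch_normalized(is_areas, samples)
  study <- norm[norm$sample_type == "study", ]
  is_names <- unique(study$is_name)
  tests <- list()
  flags <- list()
  for (is_nm in is_names) {
    sub <- study[study$is_name == is_nm, ]
    chunks <- if (scope == "pooled") list(all = sub) else
      split(sub, sub$batch_id)
    for (nm in names(chunks)) {
      ch <- chunks[[nm]]
      if (nrow(ch) < 3L) next
      gt <- grubbs_test(ch$value, alpha = alpha)
      flagged <- if (!is.na(gt$outlier_index)) {
        ch$sample_id[gt$outlier_index]
      } else NA_character_
      tests[[length(tests) + 1L]] <- tibble(
        is_name = is_nm, scope = nm, n = nrow(ch), g = gt$g,
        critical = gt$critical, flagged_sample = flagged
      )
      if (!is.na(flagged)) {
        flags[[length(flags) + 1L]] <- tibble(sample_id = flagged,
                                              is_name = is_nm)
      }
    }
  }
  tests <- do.call(rbind, tests)
  flags <- if (length(flags) > 0L) do.call(rbind, flags) else
    tibble(sample_id = character(), is_name = character())
  flagged_per_sample <- tapply(flags$is_name, flags$sample_id,
                               function(x) length(unique(x)))
  excluded <- names(flagged_per_sample)[flagged_per_sample >=
                                          length(is_names)]
  list(tests = tests, flags = flags,
       excluded_samples = as.character(excluded),
       n_is = length(is_names))
}

#' Pooled-QC drift gates
#'
#' Checks instrument drift on the pooled-QC injections: the within-batch
#' variation of pool peak areas (RSD) must stay below `intra_area_max`
#' percent and the between-batch variation (RSD of batch means) below
#' `inter_area_max` percent. When retention times are supplied the analogous
#' gates are 0.05 min (within) and 0.2 min (between) standard deviation;
#' without RT data those gates pass trivially.
#'
#' @param areas Long area table including pool records.
#' @param samples Sample table with `sample_type` and `batch_id`.
#' @param rt Optional long table `sample_id, analyte, rt_min`.
#' @param intra_area_max,inter_area_max Area gates in percent (20 / 30).
#' @param intra_rt_max,inter_rt_max RT gates in minutes (0.05 / 0.2).
#' @return List with `area` (tibble per analyte: max within-batch RSD,
#'   between-batch RSD, pass flags), `rt` (tibble or `NULL`) and
#'   `incomplete_batches` (batches with < 2 pools).
#' @export
drift_check <- function(areas, samples, rt = NULL,
                        intra_area_max = 20, inter_area_max = 30,
                        intra_rt_max = 0.05, inter_rt_max = 0.2) {
  info <- samples[match(areas$sample_id, samples$sample_id), ]
  pools <- areas[info$sample_type == "pool", ]
  pools$batch_id <- info$batch_id[info$sample_type == "pool"]
  if (nrow(pools) == 0L) stop("no pool records found", call. = FALSE)
  pools_per_batch <- tapply(pools$sample_id, pools$batch_id,
                            function(x) length(unique(x)))
  incomplete <- names(pools_per_batch)[pools_per_batch < 2L]

  summarize_one <- function(sub) {
    by_batch <- split(sub$area, sub$batch_id)
    by_batch <- by_batch[lengths(by_batch) >= 2L]
    intra <- if (length(by_batch) > 0L) {
      max(vapply(by_batch, rsd, numeric(1)))
    } else NA_real_
    means <- tapply(sub$area, sub$batch_id, mean)
    inter <- if (length(means) >= 2L) rsd(as.numeric(means)) else NA_real_
    c(intra = intra, inter = inter)
  }
  by_analyte <- split(pools, pools$analyte)
  vals <- t(vapply(by_analyte, summarize_one, numeric(2)))
  area_tbl <- tibble(
    analyte = rownames(vals),
    intra_rsd_max = vals[, "intra"],
    inter_rsd = vals[, "inter"],
    intra_pass = vals[, "intra"] <= intra_area_max,
    inter_pass = vals[, "inter"] <= inter_area_max
  )

  rt_tbl <- NULL
  if (!is.null(rt)) {
    rinfo <- samples[match(rt$sample_id, samples$sample_id), ]
    rpools <- rt[rinfo$sample_type == "pool", ]
    rpools$batch_id <- rinfo$batch_id[rinfo$sample_type == "pool"]
    sd_one <- function(sub) {
      by_batch <- split(sub$rt_min, sub$batch_id)
      by_batch <- by_batch[lengths(by_batch) >= 2L]
      intra <- if (length(by_batch) > 0L) {
        max(vapply(by_batch, sd, numeric(1)))
      } else NA_real_
      means <- tapply(sub$rt_min, sub$batch_id, mean)
      inter <- if (length(means) >= 2L) sd(as.numeric(means)) else NA_real_
      c(intra = intra, inter = inter)
    }
    rvals <- t(vapply(split(rpools, rpools$analyte), sd_one, numeric(2)))
    rt_tbl <- tibble(
      analyte = rownames(rvals),
      intra_sd_min = rvals[, "intra"],
      inter_sd_min = rvals[, "inter"],
      intra_pass = rvals[, "intra"] <= intra_rt_max,
      inter_pass = rvals[, "inter"] <= inter_rt_max
    )
  }
  list(area = area_tbl, rt = rt_tbl, incomplete_batches = incomplete)
}

#' Full quality-control report for a cohort
#'
#' Combines the study's QC gates: per-IS RSD across batch-normalized study
#' samples (robustness gate < 30%), per-analyte RSD across batch-corrected
#' pool injections, Grubbs outlier screening on the internal standards (a
#' sample is excluded only when flagged for all ISs) and the pooled-QC
#' area drift gates.
#'
#' @param cohort A `pm_cohort` (or any list with `samples`, `areas`,
#'   `is_areas`).
#' @param alpha Grubbs significance level.
#' @param rsd_max IS / pool robustness gate in percent (default 30).
#' @return Object of class `pm_qc_report`: list with `is_rsd`, `pool_rsd`,
#'   `outliers`, `drift`, and overall `pass` flag. QC failures warn; they
#'   never stop the pipeline.
#' @export
qc_report <- function(cohort, alpha = 0.05, rsd_max = 30) {
  samples <- cohort$samples; areas <- cohort$areas
  is_areas <- cohort$is_areas

  norm_is <- .pm_is_batch_normalized(is_areas, samples)
  study_is <- norm_is[norm_is$sample_type == "study", ]
  is_rsd <- tibble(
    is_name = unique(study_is$is_name),
    rsd_pct = vapply(unique(study_is$is_name), function(nm) {
      rsd(study_is$value[study_is$is_name == nm])
    }, numeric(1))
  )
  is_rsd$pass <- is_rsd$rsd_pct <= rsd_max

  corrected <- batch_correct(areas, samples)
  info <- samples[match(corrected$sample_id, samples$sample_id), ]
  pool_part <- corrected[info$sample_type == "pool", ]
  pool_rsd <- tibble(
    analyte = unique(pool_part$analyte),
    rsd_pct = vapply(unique(pool_part$analyte), function(a) {
      rsd(pool_part$area[pool_part$analyte == a])
    }, numeric(1))
  )
  pool_rsd$pass <- pool_rsd$rsd_pct <= rsd_max

  outliers <- screen_is_outliers(samples, is_areas, alpha = alpha)
  drift <- drift_check(areas, samples)

  fails <- c(
    if (any(!is_rsd$pass)) "IS RSD gate",
    if (any(!pool_rsd$pass)) "pool RSD gate",
    if (length(outliers$excluded_samples) > 0L) "IS outlier exclusion",
    if (any(!drift$area$intra_pass | !drift$area$inter_pass, na.rm = TRUE))
      "pool drift gate"
  )
  if (length(fails) > 0L) {
    warning("QC criteria not met: ", paste(fails, collapse = "; "),
            call. = FALSE)
  }
  structure(
    list(is_rsd = is_rsd, pool_rsd = pool_rsd, outliers = outliers,
         drift = drift, pass = length(fails) == 0L),
    class = "pm_qc_report"
  )
}
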