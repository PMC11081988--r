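# Normalization strategies evaluated in the study: pooled-QC batch
# correction (the basis of the final data evaluation), internal-standard
# normalization, and probabilistic quotient normalization (PQN). All
# transforms are ratio-based, so peak areas must be strictly positive.

.pm_check_area_table <- function(areas) {
  need <- c("sample_id", "analyte", "area")
  missing_cols <- setdiff(need, names(areas))
  if (length(missing_cols) > 0L) {
    stop("area table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(areas$area) | areas$area <= 0)) {
    bad <- areas$sample_id[!is.finite(areas$area) | areas$area <= 0]
    stop("non-positive or missing peak area(s), e.g. sample ",
         head(bad, 1L), "; ratio-based normalization requires positive areas",
         call. = FALSE)
  }
  invisible(areas)
}

#' Normalization mode of a normalized table
#'
#' @param x Table returned by [batch_correct()], [is_normalize()] or
#'   [pqn_normalize()].
#' @return `"batch_only"`, `"is_norm"` or `"pqn"` (or `NULL`).
#' @export
norm_mode <- function(x) attr(x, "pm_mode", exact = TRUE)

#' Per-sample PQN dilution factors of a PQN-normalized table
#'
#' @param x Table returned by [pqn_normalize()].
#' @return Tibble `sample_id`, `pqn_factor`.
#' @export
pqn_factors <- function(x) attr(x, "pm_pqn_factors", exact = TRUE)

#' Per-(batch, analyte) pool means used for batch correction
#'
#' @param x Table returned by [batch_correct()].
#' @return Tibble `batch_id`, `analyte`, `pool_mean`.
#' @export
pool_means <- function(x) attr(x, "pm_pool_means", exact = TRUE)

#' Pooled-QC batch correction
#'
#' Divides every peak area by the mean pool-sample area of the same analyte
#' within the same measurement batch. Pool records are normalized by their
#' own batch mean, so each batch's pool mean is exactly 1 per analyte after
#' correction.
#'
#' @param areas Long area table (`sample_id`, `analyte`, `area`).
#' @param samples Sample table with `sample_id`, `batch_id`, `sample_type`
#'   (pools identified by `sample_type == "pool"`).
#' @return Tibble of the same shape with corrected areas; attributes carry
#'   the mode and the pool means (see [pool_means()]).
#' @export
batch_correct <- function(areas, samples) {
  .pm_check_area_table(areas)
  info <- samples[match(areas$sample_id, samples$sample_id), ]
  if (any(is.na(info$sample_id))) {
    stop("area table contains sample_id(s) absent from the sample table",
         call. = FALSE)
  }
  key <- paste(info$batch_id, areas$analyte, sep = "\r")
  pool_rows <- info$sample_type == "pool"
  pm <- tapply(areas$area[pool_rows], key[pool_rows], mean)
  vals <- as.numeric(pm[key])
  if (any(is.na(vals))) {
    miss <- unique(key[is.na(vals)])[1L]
    parts <- strsplit(miss, "\r", fixed = TRUE)[[1L]]
    stop("no pool record for batch '", parts[1L], "', analyte '",
         parts[2L], "'", call. = FALSE)
  }
  out <- tibble(sample_id = areas$sample_id, analyte = areas$analyte,
                area = areas$area / vals)
  pm_keys <- strsplit(names(pm), "\r", fixed = TRUE)
  attr(out, "pm_pool_means") <- tibble(
    batch_id = vapply(pm_keys, `[`, character(1), 1L),
    analyte = vapply(pm_keys, `[`, character(1), 2L),
    pool_mean = as.numeric(pm)
  )
  attr(out, "pm_mode") <- "batch_only"
  out
}

#' Default analyte-to-internal-standard map
#'
#' The study spiked three isotope-labelled internal standards. Analytes with
#' a matching IS use it (creatinine, arginine, phenylalanine); all other
#' analytes fall back to phenylalanine-D1 as a general IS.
#'
#' @param analytes Character vector of analyte names.
#' @return Named character vector analyte -> IS name.
#' @export
default_is_map <- function(analytes) {
  map <- setNames(rep("phenylalanine_d1", length(analytes)), analytes)
  map[analytes == "Creatinine"] <- "creatinine_d3"
  map[analytes == "Arginine"] <- "arginine_13c6"
  map[analytes == "Phenylalanine"] <- "phenylalanine_d1"
  map
}

#' Internal-standard normalization
#'
#' Divides each analyte's peak area by the area of its mapped internal
#' standard in the same sample. Analytes without an entry in `is_map` fall
#' back to `default_is` with a notice.
#'
#' @param areas Long area table.
#' @param is_areas Long IS table (`sample_id`, `is_name`, `area`).
#' @param is_map Named character vector analyte -> IS name (default
#'   [default_is_map()] over the analytes present).
#' @param default_is Fallback IS for unmapped analytes.
#' @return Tibble of the same shape with IS-normalized values.
#' @export
is_normalize <- function(areas, is_areas,
                         is_map = default_is_map(unique(areas$analyte)),
                         default_is = "phenylalanine_d1") {
  .pm_check_area_table(areas)
  analytes <- unique(areas$analyte)
  unmapped <- setdiff(analytes, names(is_map))
  if (length(unmapped) > 0L) {
    message("no IS mapping for ", length(unmapped),
            " analyte(s); falling back to ", default_is)
    is_map <- c(is_map, setNames(rep(default_is, length(unmapped)), unmapped))
  }
  mapped_is <- as.character(is_map[areas$analyte])
  is_key <- paste(is_areas$sample_id, is_areas$is_name, sep = "\r")
  idx <- match(paste(areas$sample_id, mapped_is, sep = "\r"), is_key)
  is_vals <- is_areas$area[idx]
  bad <- is.na(is_vals) | is_vals <= 0
  if (any(bad)) {
    stop("missing or non-positive IS area for sample(s): ",
         paste(head(unique(areas$sample_id[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble(sample_id = areas$sample_id, analyte = areas$analyte,
                area = areas$area / is_vals)
  attr(out, "pm_mode") <- "is_norm"
  out
}

#' Probabilistic quotient normalization (PQN)
#'
#' For each sample, computes the quotient of every analyte's value to a
#' reference spectrum and divides the sample by the median quotient - its
#' individual dilution factor. Intended to be applied to batch-corrected
#' data; the default reference is the mean spectrum of the (batch-corrected)
#' pool injections, configurable to the median spectrum of all samples.
#'
#' @param areas Long (batch-corrected) area table.
#' @param samples Sample table (required for the `"pool_mean"` reference).
#' @param reference `"pool_mean"` (default) or `"median_all"`.
#' @return Tibble of the same shape with PQN-normalized values; the
#'   per-sample factors are available via [pqn_factors()].
#' @export
pqn_normalize <- function(areas, samples = NULL,
                          reference = c("pool_mean", "median_all")) {
  reference <- match.arg(reference)
  .pm_check_area_table(areas)
  if (length(unique(areas$analyte)) < 2L) {
    stop("PQN needs at least 2 analytes (median of quotients)",
         call. = FALSE)
  }
  if (reference == "pool_mean") {
    if (is.null(samples)) {
      stop("`samples` is required for the pool_mean reference",
           call. = FALSE)
    }
    info <- samples[match(areas$sample_id, samples$sample_id), ]
    pool_rows <- info$sample_type == "pool"
    if (!any(pool_rows)) stop("no pool records found", call. = FALSE)
    ref <- tapply(areas$area[pool_rows], areas$analyte[pool_rows], mean)
  } else {
    ref <- tapply(areas$area, areas$analyte, median)
  }
  quot <- areas$area / as.numeric(ref[areas$analyte])
  factors <- tapply(quot, areas$sample_id, median)
  fac_vals <- as.numeric(factors[areas$sample_id])
  out <- tibble(sample_id = areas$sample_id, analyte = areas$analyte,
                area = areas$area / fac_vals)
  attr(out, "pm_pqn_factors") <- tibble(
    sample_id = names(factors),
    pqn_factor = as.numeric(factors)
  )
  attr(out, "pm_reference") <- tibble(analyte = names(ref),
                                      ref = as.numeric(ref))
  attr(out, "pm_mode") <- "pqn"
  out
}
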