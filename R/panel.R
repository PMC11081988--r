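# Panel registry: the endogenous-compound panel with physicochemical
# metadata, loaded from a CSV file. The shipped default panel holds the 38
# compounds of the study (amino acids, acylcarnitines, phospholipids, bile
# acids and others) with sum formulas, accurate masses, HMDB logP values and
# retention times in the two chromatography modes (RP and HILIC).

.pm_panel_required_cols <- c("name", "compound_class")
.pm_panel_numeric_cols <- c(
  "accurate_mass", "logp", "rt_rp_min", "rt_hilic_min",
  "paired_median_pct", "unpaired_highest_pct"
)

#' Load an analyte panel from CSV
#'
#' Reads a panel table (one row per analyte) and derives per-row monoisotopic
#' masses from the sum formulas. Empty cells map to `NA` ("absent"), never to
#' zero. For rows carrying both a formula and a printed accurate mass the two
#' are reconciled: rows matching the neutral formula mass within 2e-5 Da are
#' flagged `mass_convention = "neutral"`, rows matching the formula mass
#' minus one electron mass (protonated even-electron cation, as printed for
#' the long-chain acylcarnitines) are flagged `"cation"`.
#'
#' @param path Path to a CSV file with at least columns `name` and
#'   `compound_class`; recognised optional columns are `sum_formula`,
#'   `accurate_mass`, `logp`, `logp_predicted`, `rt_rp_min`, `rt_hilic_min`
#'   plus study summary columns (`paired_median_pct`, `paired_sig`,
#'   `unpaired_highest_pct`, `unpaired_highest_group`, `unpaired_sig`,
#'   `pattern`). Retention-time placeholders `"n.d"`/`"n.e"` map to `NA`.
#' @return A tibble with one row per analyte, including derived columns
#'   `mw` (computed monoisotopic mass in Da, on the printed convention) and
#'   `mass_convention`.
#' @export
#' @examples
#' panel <- pm_panel()
#' nrow(panel)  # 38
load_panel <- function(path) {
  if (!file.exists(path)) {
    stop("panel file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = TRUE)
  missing_cols <- setdiff(.pm_panel_required_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$name <- trimws(raw$name)
  if (anyDuplicated(raw$name)) {
    dup <- unique(raw$name[duplicated(raw$name)])
    stop("duplicate analyte name(s) in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  blank_to_na <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "n.d", "n.e", "n.d.", "n.e.", "NA")] <- NA_character_
    x
  }
  for (col in names(raw)) raw[[col]] <- blank_to_na(raw[[col]])
  for (col in intersect(.pm_panel_numeric_cols, names(raw))) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(val))
    if (length(bad) > 0L) {
      stop("malformed numeric cell in panel column '", col, "', row ",
           bad[1L], " ('", raw$name[bad[1L]], "'): '", raw[[col]][bad[1L]],
           "'", call. = FALSE)
    }
    raw[[col]] <- val
  }
  if ("logp_predicted" %in% names(raw)) {
    raw$logp_predicted <- toupper(raw$logp_predicted) %in% c("TRUE", "T", "1")
  }
  if (!"sum_formula" %in% names(raw)) raw$sum_formula <- NA_character_

  n <- nrow(raw)
  mw <- rep(NA_real_, n)
  convention <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    f <- raw$sum_formula[i]
    if (is.na(f)) next
    neutral <- monoisotopic_mass(f)
    printed <- if ("accurate_mass" %in% names(raw)) raw$accurate_mass[i] else NA_real_
    if (!is.na(printed)) {
      if (abs(neutral - printed) <= 2e-5) {
        convention[i] <- "neutral"
      } else if (abs((neutral - .pm_electron_mass) - printed) <= 2e-5) {
        convention[i] <- "cation"
      } else {
        stop("computed monoisotopic mass of '", raw$name[i], "' (", f,
             ") disagrees with the printed accurate mass by ",
             signif(abs(neutral - printed), 3),
             " Da; neither neutral nor cation convention fits",
             call. = FALSE)
      }
    } else {
      convention[i] <- "neutral"
    }
    mw[i] <- monoisotopic_mass(f, convention = convention[i])
  }
  raw$mw <- mw
  raw$mass_convention <- convention
  as_tibble(raw)
}

#' The shipped 38-compound study panel
#'
#' Convenience accessor for the default panel installed with the package:
#' 38 endogenous compounds covering amino acids, acylcarnitines (C0-C18),
#' (lyso)phospholipids, a bile acid, a steroid, nucleo-compounds, taurine
#' and kynurenine, with sum formulas, accurate masses, logP (flagged
#' experimental vs predicted), retention times in RP and HILIC mode, the
#' study's published median percent changes and the four-pattern temporal
#' class of each compound.
#'
#' @return A tibble with 38 rows; see [load_panel()] for columns.
#' @export
pm_panel <- function() {
  path <- system.file("extdata", "analyte_panel.csv", package = "pmimetab",
                      mustWork = TRUE)
  load_panel(path)
}
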