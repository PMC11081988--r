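# Sum-formula parsing and monoisotopic mass computation for the panel
# registry. Masses use one fixed table of lightest-isotope atomic masses
# (CODATA/AME 2020 values, >= 9 significant figures) so that results are
# bit-reproducible.

# lightest-isotope atomic masses [Da]; 12C is exact by definition
.pm_atomic_masses <- c(
  C = 12,
  H = 1.00782503,
  N = 14.00307400,
  O = 15.99491462,
  S = 31.97207100,
  P = 30.97376200
)

# mass of the electron [Da]; protonated even-electron cations printed by
# some sources weigh the formula sum minus one electron
.pm_electron_mass <- 0.000548580

#' Atomic masses used for monoisotopic mass computation
#'
#' Returns the fixed table of lightest-isotope atomic masses (Da) used by
#' [monoisotopic_mass()]. Only the elements occurring in the shipped panel
#' ({C, H, N, O, S, P}) are supported.
#'
#' @return Named numeric vector of atomic masses in Da.
#' @export
#' @examples
#' atomic_masses()[["S"]]
atomic_masses <- function() {
  .pm_atomic_masses
}

#' Parse a molecular sum formula
#'
#' Parses a Hill-style sum formula such as `"C3H7NO2"` into element counts.
#' Implicit counts of 1 are allowed (`"S"` is `{S: 1}`); repeated element
#' symbols are summed. Only the elements C, H, N, O, S and P are accepted,
#' matching the shipped endogenous-compound panel.
#'
#' @param formula Single non-empty character string.
#' @return Named integer vector of strictly positive element counts, in
#'   canonical Hill order (C first, then H, then the rest alphabetically;
#'   all-alphabetical when no carbon is present).
#' @seealso [monoisotopic_mass()], [formula_string()]
#' @export
#' @examples
#' parse_formula("C3H7NO2")
#' parse_formula("S")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("`formula` must be a single non-empty string", call. = FALSE)
  }
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    bad <- substr(gsub("([A-Z][a-z]?[0-9]*)", "", formula), 1L, 8L)
    stop("cannot parse formula '", formula, "': unexpected token '", bad, "'",
         call. = FALSE)
  }
  elements <- sub("[0-9]+$", "", tokens)
  counts <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(counts == "", "1", counts)
  counts <- as.integer(counts)
  unknown <- setdiff(elements, names(.pm_atomic_masses))
  if (length(unknown) > 0L) {
    stop("unknown element symbol in '", formula, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts <= 0L)) {
    bad <- tokens[counts <= 0L]
    stop("element count must be a positive integer in '", formula, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  out <- setNames(as.integer(out), names(out))
  out[.pm_hill_order(names(out))]
}

# Hill convention ordering of element symbols
.pm_hill_order <- function(elements) {
  if ("C" %in% elements) {
    rest <- sort(setdiff(elements, c("C", "H")))
    intersect(c("C", "H", rest), elements)
  } else {
    sort(elements)
  }
}

#' Canonical Hill-order string of element counts
#'
#' Inverse of [parse_formula()]: renders element counts back into a
#' canonical formula string, omitting counts of 1.
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return Single character string.
#' @export
#' @examples
#' formula_string(parse_formula("H7C3NO2"))  # "C3H7NO2"
formula_string <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("`counts` must be a named vector of element counts", call. = FALSE)
  }
  counts <- counts[.pm_hill_order(names(counts))]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a sum formula
#'
#' Sums the lightest-isotope atomic masses (see [atomic_masses()]) over all
#' atoms in the formula. For `convention = "cation"` the mass of one
#' electron is subtracted, giving the mass of the even-electron protonated
#' cation when the formula itself already includes the extra proton (the
#' convention used for the long-chain acylcarnitine panel entries).
#'
#' @param formula Sum formula string, e.g. `"C4H7N3O"`.
#' @param convention `"neutral"` (default) or `"cation"`.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C3H7NO2")          # alanine, 89.047678
#' monoisotopic_mass("C23H46NO4", "cation")  # palmitoylcarnitine as printed
monoisotopic_mass <- function(formula, convention = c("neutral", "cation")) {
  convention <- match.arg(convention)
  counts <- parse_formula(formula)
  mass <- sum(.pm_atomic_masses[names(counts)] * counts)
  if (convention == "cation") {
    mass <- mass - .pm_electron_mass
  }
  unname(mass)
}
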