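# Small cohort fixtures, built in code.

# a handful of panel analyte names for cheap cohorts
tiny_analytes <- function(n = 4) pm_panel()$name[seq_len(n)]

# named list of identical kinetic models over `analytes`
uniform_kinetics <- function(analytes, ...) {
  out <- lapply(analytes, function(a) kinetic_model(...))
  names(out) <- analytes
  out
}

# deterministic cohort: all noise off, stable kinetics unless given
noise_free_cohort <- function(n_cases = 12, analytes = tiny_analytes(),
                              kinetics = NULL, seed = 1, ...) {
  if (is.null(kinetics)) {
    kinetics <- uniform_kinetics(analytes, pattern = "stable",
                                 sigma_inter = 0, sigma_intra = 0)
  }
  args <- utils::modifyList(
    list(n_cases = n_cases, n_batches = 3, sigma_batch = 0, sigma_prep = 0,
         sigma_intra_is = 0, seed = seed),
    list(...)
  )
  generate_cohort(do.call(cohort_config, args), kinetics)
}
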