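paired_edges <- bin_scheme("paired_dt")$edges[-1]

test_that("pattern rules reproduce the four-class taxonomy", {
  flat <- classify_pattern(rep(0, 9))
  expect_equal(flat$pattern, "stable")
  expect_equal(flat$confidence, "high")

  steady <- classify_pattern(c(5, 10, 25, 60, 120, 160),
                             upper_edges_h = paired_edges[1:6])
  expect_equal(steady$pattern, "steady_increase")

  lag <- classify_pattern(c(2, -3, 4, 45, 80, 120),
                          upper_edges_h = paired_edges[1:6])
  expect_equal(lag$pattern, "lag_then_increase")

  dec <- classify_pattern(c(-5, -12, -20, -35, -50, -60),
                          upper_edges_h = paired_edges[1:6])
  expect_equal(dec$pattern, "decrease")

  # empty bins (NA) are dropped together with their edges
  with_na <- classify_pattern(c(2, NA, 4, 45, NA, 80, 120, NA, NA))
  expect_equal(with_na$pattern, "lag_then_increase")

  expect_error(classify_pattern(c(0, 10, 20), upper_edges_h = c(12, 24, 36)),
               "at least 4")

  # non-monotone profile ending in-band: falls back with low confidence
  odd <- classify_pattern(c(-40, 20, 10, 0, 5, -10),
                          upper_edges_h = paired_edges[1:6])
  expect_equal(odd$confidence, "low")

  # classification is invariant to uniform scaling of all areas (percent
  # changes are scale-free): same medians, same call
  m <- c(3, 8, 12, 40, 90, 150)
  a <- classify_pattern(m, upper_edges_h = paired_edges[1:6])
  expect_equal(a$pattern, "lag_then_increase")
})

test_that("per-analyte classification recovers well-separated generator
          patterns", {
  cohort <- generate_cohort(cohort_config(seed = 81),
                            kinetics_well_separated(tiny_analytes(8)))
  ps <- run_paired_stage(cohort$areas, cohort$pairs, tests = FALSE)
  pat <- classify_patterns(ps)
  truth <- cohort$truth$analytes
  expect_equal(pat$pattern[match(truth$analyte, pat$analyte)],
               truth$pattern)
})

test_that("property correlations use available pairs and track planted
          dependence", {
  panel <- pm_panel()
  # change equal to the property itself: perfect rank correlation
  changes <- tibble::tibble(analyte = panel$name, change = panel$logp)
  res <- correlate_properties(changes, panel, "logp")
  expect_equal(res$rho, 1)
  expect_equal(res$n, sum(!is.na(panel$logp)))
  expect_equal(res$n_excluded, sum(is.na(panel$logp)))

  # change assigned independently of the property: near-zero mean rho
  set.seed(82)
  rhos <- replicate(200, {
    shuffled <- tibble::tibble(analyte = panel$name,
                               change = sample(panel$paired_median_pct))
    correlate_properties(shuffled, panel, "logp")$rho
  })
  expect_lt(abs(mean(rhos)), 0.08)

  expect_error(
    correlate_properties(changes[1:2, ], panel, "logp"),
    "fewer than 3"
  )
})

test_that("paired/unpaired concordance is exact on identical inputs and
          validates analyte sets", {
  analytes <- sprintf("a%02d", 1:10)
  vals <- seq(-60, 160, length.out = 10)
  paired_summary <- tibble::tibble(
    analyte = analytes, bin = "all", n_pairs = 50L, median_pct = vals,
    ci_low = vals, ci_high = vals, statistic = 1, p_raw = 0.01,
    p_adj = 0.02, code = "*"
  )
  labels <- bin_scheme("unpaired_tod")$labels
  groups <- tibble::tibble(
    analyte = rep(analytes, each = 10),
    group = factor(rep(labels, 10), levels = labels),
    n = 10L, median_area = 1,
    pct_vs_group1 = as.vector(vapply(vals, function(v) {
      c(0, seq(v / 9, v, length.out = 9))
    }, numeric(10)))
  )
  res <- paired_unpaired_concordance(paired_summary, groups)
  expect_equal(res$rho_sq, 1)
  expect_equal(res$n, 10)

  expect_error(
    paired_unpaired_concordance(paired_summary[1:8, ], groups),
    "analyte sets differ"
  )

  # a constant side has no rank variance: degenerate
  paired_const <- paired_summary
  paired_const$median_pct <- 0
  expect_error(paired_unpaired_concordance(paired_const, groups),
               "degenerate")
})

test_that("normalization modes agree without prep variation or drift and
          PQN attenuates many-analyte drift", {
  # no drift, no prep variation: all three modes give the same flat answer
  quiet <- generate_cohort(
    cohort_config(n_cases = 30, n_batches = 3, sigma_prep = 0, seed = 83),
    uniform_kinetics(tiny_analytes(4), "stable", sigma_intra = 0.05)
  )
  cmp <- compare_normalization_modes(quiet, run_unpaired = FALSE)
  meds <- vapply(cmp$paired, function(s) s$median_pct[1], numeric(1))
  expect_true(all(abs(meds) < 15))
  expect_lt(max(meds) - min(meds), 15)

  # 30 of 38 analytes drifting: PQN attenuates the recovered change
  panel_names <- pm_panel()$name
  kin <- c(
    uniform_kinetics(panel_names[1:30], "steady_increase", rate = 1 / 71),
    uniform_kinetics(panel_names[31:38], "stable")
  )
  drifty <- generate_cohort(cohort_config(n_cases = 80, seed = 84), kin)
  cmp2 <- compare_normalization_modes(drifty, c("batch_only", "pqn"),
                                      run_unpaired = FALSE)
  expect_lt(cmp2$attenuation$median_ratio, 1)
  expect_true(all(cmp2$attenuation$ratios$analyte %in% panel_names[1:30]))

  # prep-factor variation only: IS and PQN tighten the paired spread
  prep <- generate_cohort(
    cohort_config(n_cases = 60, n_batches = 3, sigma_prep = 0.4, seed = 85),
    uniform_kinetics(tiny_analytes(6), "stable", sigma_intra = 0.02)
  )
  cmp3 <- compare_normalization_modes(prep, run_unpaired = FALSE)
  spread <- function(mode) {
    tab <- switch(mode,
      batch_only = batch_correct(prep$areas, prep$samples),
      is = is_normalize(prep$areas, prep$is_areas),
      pqn = pqn_normalize(batch_correct(prep$areas, prep$samples),
                          prep$samples))
    ct <- pair_changes(tab, prep$pairs)
    stats::IQR(ct$pct_change)
  }
  expect_lt(spread("is"), spread("batch_only"))
  expect_lt(spread("pqn"), spread("batch_only"))
})

test_that("cross-platform concordance flags sign-flipped analytes", {
  analytes <- c("Proline", "Lysine", "Taurine")
  bins <- bin_scheme("paired_dt")$labels
  prof <- function(vals) {
    tibble::tibble(
      analyte = rep(analytes, each = length(bins)),
      bin = rep(bins, length(analytes)),
      n_pairs = 20L,
      median_pct = as.vector(vals)
    )
  }
  base <- vapply(1:3, function(i) seq(5, 120, length.out = length(bins)) * i,
                 numeric(length(bins)))
  rp <- prof(base)
  identical_res <- cross_platform_concordance(rp, rp)
  expect_equal(identical_res$rho, rep(1, 3))
  expect_false(any(identical_res$discordant))

  flipped <- base
  flipped[, 1] <- -flipped[, 1]  # proline inverts between platforms
  hilic <- prof(flipped)
  res <- cross_platform_concordance(rp, hilic)
  expect_true(res$discordant[res$analyte == "Proline"])
  expect_false(any(res$discordant[res$analyte != "Proline"]))

  other <- prof(base)
  other$analyte <- rep(c("x", "y", "z"), each = length(bins))
  expect_error(cross_platform_concordance(rp, other), "no overlapping")
})
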