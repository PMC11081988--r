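make_unpaired_cohort <- function(seed = 71, rate = 1 / 50, n_cases = 120) {
  kin <- c(
    uniform_kinetics(tiny_analytes(2)[1], "steady_increase", rate = rate),
    uniform_kinetics(tiny_analytes(2)[2], "stable")
  )
  generate_cohort(cohort_config(n_cases = n_cases, n_batches = 6,
                                seed = seed), kin)
}

test_that("group profiles track a monotone drift and are zero for group 1", {
  cohort <- make_unpaired_cohort()
  norm <- batch_correct(cohort$areas, cohort$samples)
  res <- run_unpaired_stage(norm, cohort$samples)
  drifting <- tiny_analytes(2)[1]
  g <- res$groups[res$groups$analyte == drifting & res$groups$n > 0, ]
  g <- g[order(as.integer(g$group)), ]
  expect_equal(g$pct_vs_group1[1], 0)
  # profile rises across groups for a steady increase (rank correlation
  # under noise; exact monotonicity is asserted noise-free below)
  expect_gt(spearman_rank(seq_len(nrow(g)), g$pct_vs_group1)$rho, 0.9)
  expect_gt(g$pct_vs_group1[nrow(g)], 100)

  # noise-free: group medians of a steady increase rise strictly
  nf <- noise_free_cohort(
    n_cases = 80,
    kinetics = uniform_kinetics(tiny_analytes(1), "steady_increase",
                                rate = 1 / 50, sigma_inter = 0,
                                sigma_intra = 0),
    seed = 75
  )
  nf_res <- run_unpaired_stage(batch_correct(nf$areas, nf$samples),
                               nf$samples)
  nf_g <- nf_res$groups[nf_res$groups$n > 0, ]
  nf_g <- nf_g[order(as.integer(nf_g$group)), ]
  expect_true(all(diff(nf_g$pct_vs_group1) > 0))
  # Kruskal-Wallis flags the drifting analyte, Holm-adjusted
  kw <- res$kw
  expect_lt(kw$p_adj[kw$analyte == drifting], 0.001)
  # Dunn runs only on gated analytes
  expect_true(all(res$dunn$analyte %in%
                    kw$analyte[kw$p_adj < 0.05]))
  # late-vs-early cells significant, adjacent early cells not
  d <- res$dunn[res$dunn$analyte == drifting, ]
  late <- d$p_adj[d$group_i == "0-6 h" & d$group_j == ">144 h"]
  expect_lt(late, 0.05)
  early <- d$p_adj[d$group_i == "0-6 h" & d$group_j == "6-12 h"]
  expect_gt(early, 0.05)
  # the Dunn matrix respects p_adj >= p_raw cellwise
  expect_true(all(res$dunn$p_adj >= res$dunn$p_raw))
})

test_that("the unpaired stage is invariant to row order", {
  cohort <- make_unpaired_cohort(seed = 72, n_cases = 40)
  norm <- batch_correct(cohort$areas, cohort$samples)
  res1 <- run_unpaired_stage(norm, cohort$samples)
  shuffled <- norm[sample(nrow(norm)), ]
  res2 <- run_unpaired_stage(shuffled, cohort$samples)
  expect_equal(res2$kw, res1$kw)
  g1 <- res1$groups[order(res1$groups$analyte, res1$groups$group), ]
  g2 <- res2$groups[order(res2$groups$analyte, res2$groups$group), ]
  expect_equal(g2$median_area, g1$median_area)
})

test_that("cases binned into the same group are counted", {
  cohort <- make_unpaired_cohort(seed = 73, n_cases = 60)
  norm <- batch_correct(cohort$areas, cohort$samples)
  res <- run_unpaired_stage(norm, cohort$samples)
  scheme <- bin_scheme("unpaired_tod")
  expected <- sum(assign_bin(cohort$pairs$t1_h, scheme) ==
                    assign_bin(cohort$pairs$t2_h, scheme))
  expect_equal(res$same_group_cases$n, expected)
})

test_that("highest change picks the largest absolute deviation from group 1
          with late tie-breaks", {
  groups <- tibble::tibble(
    analyte = "X",
    group = factor(bin_scheme("unpaired_tod")$labels,
                   levels = bin_scheme("unpaired_tod")$labels),
    n = rep(10L, 10),
    median_area = 1,
    pct_vs_group1 = c(0, 5, 10, 20, 35, 80, 120, 90, 60, 40)
  )
  hc <- highest_change(groups)
  expect_equal(hc$highest_pct, 120)
  expect_equal(hc$group, "72-96 h")  # peak at group 7, then decline
  expect_false(hc$flat)

  # monotone profile: last populated group wins
  groups$pct_vs_group1 <- c(0, 1, 2, 4, 8, 16, 32, 64, 128, 256)
  expect_equal(highest_change(groups)$group, ">144 h")

  # tie between a negative and an equal positive value: later group
  groups$pct_vs_group1 <- c(0, -50, 0, 0, 0, 0, 0, 0, 0, 50)
  expect_equal(highest_change(groups)$group, ">144 h")

  # all-zero profile: flat flag, earliest non-group-1 label
  groups$pct_vs_group1 <- rep(0, 10)
  hc0 <- highest_change(groups)
  expect_true(hc0$flat)
  expect_equal(hc0$highest_pct, 0)
  expect_equal(hc0$group, "6-12 h")
})

test_that("the sampling-procedure check detects a planted one-sided shift", {
  # build a balanced 24-36 h bin directly: 33 t1 vs 45 t2 samples
  set.seed(74)
  n1 <- 33; n2 <- 45
  samples <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n1 + n2)),
    case_id = sprintf("c%03d", seq_len(n1 + n2)),
    timepoint_label = c(rep("t1", n1), rep("t2", n2)),
    sample_type = "study",
    batch_id = "B1",
    time_since_death_h = runif(n1 + n2, 24, 36)
  )
  analytes <- sprintf("a%02d", 1:20)
  shifted <- analytes[1:12]
  rows <- expand.grid(sample_id = samples$sample_id, analyte = analytes,
                      stringsAsFactors = FALSE)
  rows$area <- exp(rnorm(nrow(rows), log(1e6), 0.15))
  t2_rows <- rows$sample_id %in% samples$sample_id[samples$timepoint_label ==
                                                     "t2"]
  plant <- t2_rows & rows$analyte %in% shifted
  rows$area[plant] <- rows$area[plant] * (1 - 0.31)
  res <- compare_sampling_procedures(tibble::as_tibble(rows), samples)
  hit <- res$analyte[res$p_adj < 0.05]
  expect_setequal(hit, shifted)
  expect_true(all(res$median_diff_pct[res$analyte %in% shifted] < 0))
  expect_equal(median(res$median_diff_pct[res$analyte %in% shifted]), -31,
               tolerance = 0.15)

  # identical group multisets: all p = 1
  eq_samples <- tibble::tibble(
    sample_id = sprintf("e%02d", 1:20),
    case_id = sprintf("c%02d", 1:20),
    timepoint_label = rep(c("t1", "t2"), each = 10),
    sample_type = "study", batch_id = "B1",
    time_since_death_h = seq(24.5, 35.5, length.out = 20)
  )
  eq_rows <- expand.grid(sample_id = eq_samples$sample_id,
                         analyte = c("a1", "a2"), stringsAsFactors = FALSE)
  eq_rows$area <- rep(rep(1:10, 2), 2)  # same multiset in both groups
  res0 <- compare_sampling_procedures(tibble::as_tibble(eq_rows), eq_samples)
  expect_equal(res0$p_raw, rep(1, 2))

  # a bin lacking one label errors
  t1_only <- samples[samples$timepoint_label == "t1", ]
  expect_error(
    compare_sampling_procedures(
      tibble::as_tibble(rows[rows$sample_id %in% t1_only$sample_id, ]),
      t1_only),
    "lacks t1 or t2"
  )
})
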