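# pmimetab

Time-since-death analysis of endogenous compounds in paired postmortem
femoral blood.

## What it is for

In forensic metabolomics the postmortem interval (PMI) — the time between
death and blood collection — is itself a major driver of measured
metabolite levels. `pmimetab` is for analysts who work with targeted
LC-HRMS peak areas from postmortem femoral blood collected twice per case
(at mortuary admission, t1, and at autopsy, t2) and who want to quantify
and control that time effect. It implements the complete chain:

* a 38-compound panel registry (amino acids, acylcarnitines C0–C18,
  (lyso)phospholipids, bile acid, steroid, nucleo-compounds) with
  sum-formula parsing and monoisotopic mass computation;
* a synthetic cohort generator reproducing the study design (427 paired
  cases, 17 batches × 5 pooled-QC injections, three isotope-labelled
  internal standards, four temporal drift patterns) with ground truth for
  every simulated effect;
* quality control: single-pass Grubbs screening on batch-normalized
  internal standards (a sample is excluded only when flagged on **all**
  ISs), RSD gates, pooled-QC drift gates;
* normalization: pooled-QC batch correction, internal-standard
  normalization, probabilistic quotient normalization (PQN);
* inference: paired Wilcoxon signed-rank per Δt bin and overall, and
  Kruskal–Wallis + Dunn post-hoc across ten time-since-death groups, all
  Holm-adjusted, on a self-contained rank-statistics engine with
  exact-enumeration branches for small samples;
* interpretation: four-pattern temporal classification, correlation of
  change magnitude with logP / molecular weight / retention time,
  paired-vs-unpaired concordance, normalization-mode comparison, and
  RP-vs-HILIC trend concordance.

The core quantity is the per-case percent change
`100 · (area_t2 − area_t1) / area_t1`, computed on raw areas (both samples
of a case share a measurement batch, so batch factors cancel), summarized
per analyte by the median with a distribution-free 95% CI, and tested with
`W = min(W⁺, W⁻)` against exact or tie-corrected null distributions.

## Worked example

```r
library(pmimetab)

monoisotopic_mass("C4H7N3O")     # creatinine
#> [1] 113.0589

cohort <- generate_cohort(cohort_config(seed = 1))   # 427 paired cases
res <- run_pipeline(cohort, out_dir = "demo_out")

overall <- subset(res$paired_summary, bin == "all")
head(overall[order(-overall$median_pct),
             c("analyte", "n_pairs", "median_pct", "ci_low", "ci_high",
               "p_adj", "code")], 5)
#>   analyte              n_pairs median_pct ci_low ci_high    p_adj code
#> 1 Cholic acid              427      188.   159.    208.  9.43e-65 ***
#> 2 Taurine                  427      138.   121.    154.  4.94e-69 ***
#> 3 Carnitine (C0)           427      100.    90.6   112.  2.17e-68 ***
#> 4 Acetylcarnitine (C2)     427       85.9   77.4    99.6 6.44e-66 ***
#> 5 Alanine                  427       79.1   70.9    90.5 1.62e-65 ***

res$concordance$rho_sq          # paired vs unpaired agreement (Spearman)
#> [1] 0.9101983

table(res$patterns$pattern)     # four-pattern temporal classification
#>          decrease lag_then_increase            stable   steady_increase
#>                 4                12                14                 8
```

Reading the output: the strongest simulated increases (cholic acid +188%,
taurine +138%) are the analytes whose default kinetics were calibrated to
the largest published paired changes, and every drifting analyte is
Holm-significant at n = 427 pairs. The Spearman ρ² of 0.91 says the
per-analyte overall paired change and the largest unpaired time-group
change rank the panel almost identically — the two evaluation strategies
agree. The pattern table is the classifier's reconstruction from the
per-Δt-bin medians; `res$correlations` shows the (absent, by construction)
association between change magnitude and logP or molecular weight.
`demo_out/` contains every stage table as CSV plus `report.md` and the
effective configuration.

The generator is seeded end to end: the same `cohort_config(seed = …)`
yields byte-identical cohorts and pipeline outputs.

## Package layout

| file | contents |
|---|---|
| `R/formula.R`, `R/panel.R` | formula parser, monoisotopic masses, panel registry |
| `R/simulate.R` | kinetic models, cohort configuration, generator, ToD imputation |
| `R/qc.R` | RSD, Grubbs, IS outlier screening, drift gates |
| `R/normalize.R` | batch correction, IS normalization, PQN |
| `R/stats.R` | signed-rank, Mann–Whitney, Kruskal–Wallis, Dunn, Holm, Spearman, median CI |
| `R/bins.R`, `R/paired.R`, `R/unpaired.R` | bin schemes and the two inference stages |
| `R/interpret.R` | pattern classification, correlations, concordance, mode comparison |
| `R/pipeline.R` | validation, one-call pipeline, CSV/report output |
| `vignettes/postmortem-time-dependence.Rmd` | methods: model, parameters, conventions, limitations |
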