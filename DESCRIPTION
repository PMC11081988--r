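Package: pmimetab
Title: Time-Since-Death Analysis of Endogenous Compounds in Paired
    Postmortem Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying postmortem-interval dependent changes of
    targeted endogenous compounds (amino acids, acylcarnitines,
    phospholipids and others) in paired femoral blood samples measured by
    LC-HRMS. Provides a 38-compound panel registry with monoisotopic mass
    computation, a synthetic paired-cohort generator with pooled-QC batches
    and isotope-labelled internal standards, quality control (Grubbs
    outlier screening, RSD and drift gates), pooled-QC batch correction,
    internal-standard and probabilistic quotient normalization, paired
    (Wilcoxon signed-rank) and time-group (Kruskal-Wallis/Dunn, Holm)
    nonparametric inference, temporal pattern classification, and
    physicochemical correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
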