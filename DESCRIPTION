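Package: tmindex
Title: Tumor Mutation Index Stratification from Circulating DNA Mutation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for stratifying response to multitargeted antiangiogenic
    therapy in advanced non-small cell lung cancer from circulating DNA
    (cfDNA/ctDNA) mutation-call tables. Implements the panel/depth/VAF filter
    chain and the two plasma mutation-burden predictors (germline+somatic and
    nonsynonymous+synonymous burden), the baseline ARID1A/BRCA2 resistance
    screen and baseline-to-progression acquired-mutation analysis, a
    per-mutation survival screen yielding an Unfavorable Mutation Score (UMS),
    a minimum-p-value cutoff scan for survival biomarkers, Kaplan-Meier and
    weighted log-rank (Gehan-Breslow Wilcoxon) machinery, ROC/AUC with
    Hanley-McNeil confidence intervals, the composite Tumor Mutation Index
    (TMI) score card, and the combined TMI plus IDH1 exon-4 classifier. A
    synthetic cohort generator with planted hazard effects makes every stage
    testable end to end without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
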