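Package: medipdiff
Title: Differential DNA Methylation Analysis for MeDIP Promoter Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-colour MeDIP (methylated-DNA immunoprecipitation)
    promoter tiling-array studies: sliding-window peak detection on
    log2(MeDIP/Input) enrichment tracks, differential enrichment scoring
    between two groups (the M' statistic), median/CV-based peak filtering,
    CpG-density promoter classification (HCP/ICP/LCP), bisulfite-sequencing
    PCR clone analysis with conversion QC, and the metabolic-phenotype
    statistics that typically accompany such studies (HOMA-IR, OGTT AUC,
    comparative-Ct relative expression, two-way factorial ANOVA). A
    fully seeded synthetic-data generator emulates a two-group,
    three-replicate promoter-array design with planted differentially
    methylated regions for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    car,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
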