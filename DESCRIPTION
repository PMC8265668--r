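Package: asvscreen
Title: Negative-Control Screening and Removal of Contaminant ASVs in
    Low-Biomass 16S Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate contaminant amplicon sequence variants
    (ASVs) in low-microbial-biomass 16S rRNA gene data sets from the pooled
    relative abundance of each ASV in negative-control samples, applies
    graded removal treatments (no removal, full removal of control-detected
    ASVs, or removal at control-abundance thresholds of 1, 5, or 10
    percent), and quantifies the impact of removal on alpha and beta
    diversity with paired tests and compact letter displays.  Includes a
    prevalence-based contaminant score (one-sided chi-square/Fisher hybrid
    on presence/absence in controls versus experimental samples) for
    cross-method comparison, and a synthetic community generator that
    emulates reagent ('kitome') contamination, biomass-dependent
    bleed-through into tissue samples, and cross-contamination of true
    symbionts into controls, with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
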