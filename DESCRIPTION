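Package: lipidlsr
Title: Hierarchical Plasma Lipidome Analysis and Lipid Species Ratio Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted plasma lipidomics cohorts: lipid
    shorthand nomenclature parsing, unit conversion, blank correction and
    QC-based batch exclusion, rank-based two-step normalization, class-level
    trend statistics (Mann-Whitney U, Jonckheere-Terpstra), exploratory
    principal component clustering of lipid species with varimax rotation,
    covariate-adjusted stepwise selection of BMI-associated species, greedy
    construction of the lipid species ratio (LSR), and ROC/Youden reference
    cut-off estimation. Includes a synthetic cohort generator with planted
    effects so every stage is testable without access to private cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
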