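Package: methstab
Title: Epigenetically Stable Loci and DNA Methylation Instability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery of epigenetically stable CpG loci (ESLs) from
    healthy-cohort beta-value matrices, calibration of a destabilization
    threshold from control cohorts, per-sample DNA methylation instability
    (DMI) scoring, recurrence and lineage-enrichment classification of
    perturbed loci, diagnosis-relapse epi-clone matching with a permutation
    null, DMI-based survival stratification, and promoter-centred gene
    prioritization.  Includes a synthetic cohort generator with planted
    ground truth so every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
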