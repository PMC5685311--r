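Package: neuropanel
Title: Variant Prioritisation and Cohort Reporting for a Targeted
    Neurodegeneration Gene Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis for a custom 80-gene neurodegeneration
    resequencing panel covering Alzheimer's disease and mild cognitive
    impairment, amyotrophic lateral sclerosis, frontotemporal dementia,
    Parkinson's disease and vascular cognitive impairment. Reads per-sample
    variant calls (VCF), joins them to an annotation resource, applies
    rarity, consequence and in-silico prediction rules to dichotomise
    variants into clinically relevant versus uncertain significance, calls
    APOE E2/E3/E4 diplotypes from rs429358 and rs7412 genotypes, computes
    sequencing-run quality-control metrics, evaluates cross-platform
    genotype concordance, and produces cohort-level demographic, diagnostic
    yield and variant-origin tables. A seeded synthetic-cohort generator
    provides realistic test data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
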