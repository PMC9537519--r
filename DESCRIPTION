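Package: cnvmod
Title: Copy Number Variants as Breast Cancer Risk Modifiers in BRCA1/BRCA2 Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-centric association analysis of germline copy number
    variants (CNVs) as modifiers of breast cancer risk in BRCA1 and BRCA2
    pathogenic variant carriers. Provides post-processing of PennCNV-style
    CNV calls (sample quality control, probe-count filtering, adjacent-call
    merging), construction of subject-by-gene deletion/duplication genotype
    matrices, an ascertainment-corrected retrospective-likelihood score test
    with family-cluster-robust variance, a weighted-cohort Cox model with
    incidence-derived weights, effective-test significance thresholds,
    CNV-call concordance arithmetic against orthogonal truth sets, and a
    synthetic carrier-family cohort generator with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    survival,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
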