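Package: tripletmut
Title: Germline and Somatic Mutational Landscapes in Matched
    Blood/Normal/Tumor Exome Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-exome variant calls from matched
    blood, cancer-adjacent normal and tumor tissue ("triplet") cohorts.
    Classifies variants into germline and somatic origin classes by tissue
    presence, applies GATK-style hard filters and a high-functional-impact
    annotation filter, summarises variant allele frequencies and clonal
    sharing, tests gene-level differential mutation (Fisher's exact test
    with Benjamini-Hochberg correction and Cramer's V), attributes cancer
    hallmark pathway alterations to germline versus somatic sources,
    runs log-odds-ratio-ranked preranked gene set enrichment analysis,
    and decomposes SBS-96 mutational spectra into signature exposures by
    non-negative least squares. A synthetic triplet-cohort generator with
    full ground truth makes every stage testable without protected
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
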