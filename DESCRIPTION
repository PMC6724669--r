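Package: varmedal
Title: Germline Variant Triage with Medal Tiers and Automated ACMG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based triage and classification of germline sequence variants
    in disease-gene panels. Streams variants out of VCF, decomposes and
    normalizes alleles, filters to gene panels, applies splice-aware
    consequence adjustment and a coding/splice retention filter, matches
    variants against tab-delimited snapshots of curated variant databases,
    somatic hotspot tables, population allele frequencies and in silico
    damage predictions at graded specificity, assigns gold/silver/bronze
    triage medals with an auditable reason trail, auto-generates ACMG/AMP
    evidence tags (PVS1, PS1, PM1, PM2, PM4, PM5, BA1) and derives the
    five-tier pathogenicity classification from published combining rules.
    Includes a deterministic synthetic fixture generator exercising every
    rule path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
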