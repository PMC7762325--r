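Package: gliomaburden
Title: Mutational and Copy-Number Burden Metrics for IDH-Wild-Type Glioma Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of somatic alteration burden in
    IDH-wild-type diffuse glioma whole-exome cohorts: SNV and indel burden per
    captured megabase, the weighted Genome Instability Index (wGII), the
    chromosomal arm event ratio (CAER), copy-number amplitude, rule-based
    double-minute amplicon detection, sliding-window chromothripsis detection,
    non-negative least-squares refitting of 96-channel mutational signature
    catalogs with a 10 percent acceptance rule, molecular subset classification
    (molecularly-defined glioblastoma versus other diffuse gliomas), and the
    cohort-level statistical comparisons built on these metrics. Includes a
    synthetic cohort generator with planted ground truth that emulates the
    variant, segment and structural-variant tables of a matched tumor-normal
    exome study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
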