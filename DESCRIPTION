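Package: PMedProfiler
Title: Personalized-Medicine Drug Prediction from Tumor Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of a comparative-oncology
    personalized-medicine (PMed) workflow for tumor expression profiles.
    Tumor samples are standardized against a normal-tissue reference
    compendium as per-probe z-scores, aggregated to genes, mapped one-to-one
    across species, and scored by six drug-prediction methods: drug-target
    expression rules, sensitivity and resistance biomarker rules,
    connectivity-map style drug response signatures with permutation
    p-values, parametric gene-set enrichment against drug sensitivity
    signatures, and shortest-path network target activity. Per-method calls
    are aggregated into a ranked per-patient drug report. The package also
    provides the supporting study machinery: histopathology/RNA/cDNA/array
    QA-QC gates, business-hours turnaround accounting, classical
    multidimensional scaling of sample profiles, and a synthetic-data
    generator that emulates the study inputs with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, jsonlite, cluster
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
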