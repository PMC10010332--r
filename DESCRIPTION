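Package: lesionscope
Title: Interlesion Tumor and Immune Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing heterogeneity between metastatic lesions of
    the same patient under PD-1 blockade: consensus somatic-variant filtering
    with human and mouse presets, a tumor/normal log-R-ratio copy-number
    procedure with GC-bin depth adjustment and moving-window medians, mutant
    9-mer neoantigen enumeration with strong-binder filtering and interlesion
    Venn partitions, single-cell TCR clonotype resolution with QC, Pielou
    evenness, interlesion dominance classification and exhausted-clone
    enrichment via an exact Fisher test, and mixed-response classification of
    patient cohorts with Kaplan-Meier and log-rank survival comparison.
    Seeded synthetic-data generators emulate every input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), survival, vegan, Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
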