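Package: lohtimer
Title: Timing Mutant-Allele Copy-Number Gains in Tumor Whole Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers when a tumor gained extra copies of a mutant allele
    (for example the germline TP53 allele in Li-Fraumeni syndrome) from
    whole-genome somatic variant calls and allele-specific copy number.
    Provides the somatic SNV filter cascade, loss-of-heterozygosity state
    classification, purity-aware mutation multiplicity and cancer cell
    fraction estimation, mutational-signature refitting with per-mutation
    posteriors, clock-like (SBS1/SBS5) mutation counting, closed-form
    molecular-time estimation of copy-number gains with bootstrap
    confidence intervals, a TelSeq-style telomere content estimator, and
    a synthetic tumor generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
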