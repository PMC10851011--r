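Package: ampedit
Title: Allele-Specific CRISPR-Cas9 Editing Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies allele-specific CRISPR-Cas9 editing outcomes from deep
    amplicon sequencing of a diploid locus carrying a single discriminating
    variant. Reads are globally aligned with affine gap penalties against both
    allele references, assigned an allele of origin, and classified into
    editing-outcome classes using an editing window around the Cas9 cleavage
    site; within-window indels are reduced to canonical, left-normalized
    variant keys to build reproducible indel spectra. Additional tools score
    cryptic donor splice sites of reconstructed post-edit sequences with a
    position weight matrix, compare observed spectra against predicted indel
    profiles and across replicates, aggregate population variant frequencies
    across gnomAD-style datasets, and simulate amplicon read sets with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
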