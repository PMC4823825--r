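Package: clonetrail
Title: Multi-Region Tumor Clonal Evolution from Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the clonal evolution of a tumor from
    multi-region sequencing of one patient. Implements copy-number-aware
    correction of somatic allele read counts, arm-level copy-number calling
    from germline B-allele-frequency imbalance and tumor/normal coverage,
    clustering of mutations by cellular frequency with exhaustive clone-tree
    search under the parent-child sum condition, temporal ordering of driver
    mutations from relative allele frequencies across regions, spatial
    (ubiquitous/shared/private) and driver (main/accessory/passenger)
    classification including obligate-partner detection, and Poisson-based
    droplet digital PCR quantification. A synthetic-cohort generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
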