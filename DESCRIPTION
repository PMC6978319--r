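Package: caatools
Title: Chromosome Arm Aneuploidy Calling, Co-Occurrence and Evolution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls chromosome arm-level aneuploidies (CAAs) from segmented
    copy-number profiles using centromere-filtered arm fractions and the
    >=0.9 arm-call rule, detects whole-genome doubling from allele-specific
    copy number, computes exact expectations for intra-tumour gain:loss
    ratios, estimates the order in which CAAs are acquired during tumour
    evolution from a karyotype tree, models pairwise CAA co-occurrence with
    a combinatorial (hypergeometric-equivalent) null, and screens
    pharmacogenomic feature pairs for synthetic-lethal and
    synergistic-resistance interactions with drug response. Seeded
    synthetic-data generators emulate the statistical structure of
    segmented tumour profiles, evolving cohorts, binary event matrices and
    cell-line drug-response panels so that every stage is testable without
    external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
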