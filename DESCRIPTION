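Package: cinsig
Title: Chromosomal Instability and Mutational Signatures in Sparse Single-Cell DNA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for shallow single-cell whole-genome DNA data
    from clonally heterogeneous epithelia such as Barrett's esophagus.
    Per-cell binned read counts are median-normalised to copy number,
    cells are grouped by hierarchical clustering, cluster profiles are
    segmented by circular binary segmentation, and a chromosomally stable
    (CS) cluster is identified against the unstable (CIN) clusters.
    Variant calls pass through a filter cascade (mapping quality, germline
    blacklist, cross-patient sharing, CS overlap) followed by per-cluster
    Fisher-exact enrichment. Cluster trinucleotide spectra are normalised
    to a common depth, baseline-subtracted against the CS cluster, and
    refit by non-negative least squares against a signature catalog to
    quantify how much signatures such as SBS17a and SBS17b explain. A
    synthetic-data module simulates clonal cell populations with known
    karyotypes and signature mixtures so every stage can be verified
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
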