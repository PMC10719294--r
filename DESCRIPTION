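Package: karyograph
Title: Karyotype Evolution, Ancestral Linkage Groups and Genome Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative-genomics toolkit for chromosome-scale genome
    evolution. Reconstructs ancestral linkage groups by consensus Leiden
    community detection on an orthogroup co-linkage graph, quantifies
    macrosynteny (Oxford tables, chromosome correspondence, ALG
    projection) and microsynteny (colinear block census under an
    intervening-gene budget), detects ultraconserved elements in pairwise
    alignments by sliding-window identity extension, computes Hi-C
    insulation tracks with boundary-strength statistics, and relates
    ATAC peak-to-gene distances to genome size. Includes a karyotype
    evolution simulator (fusion, fission, translocation, transposition,
    loss, duplication) that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    GenomeInfoDb,
    igraph,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
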