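Package: isoflow
Title: RNA Isoform Identification and Quantification by Convex-Cost Network Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous identification and quantification of RNA transcript
    isoforms from single-end RNA-Seq read counts. Reads are summarised into
    "bins" (the exact ordered set of exons a read overlaps); bin counts are
    modelled as Poisson with intensity proportional to bin effective length
    and the summed abundances of the isoforms containing the bin. The
    l1-penalised Poisson maximum-likelihood estimator over the (exponentially
    large) set of candidate isoforms is solved in polynomial time as a
    convex-cost network flow problem on a directed acyclic graph of bins,
    whose source-to-sink paths are in bijection with candidate isoforms. The
    optimal flow is decomposed into path flows by iterated maximum-bottleneck
    path extraction, and the final transcript set is chosen by BIC along a
    regularisation path. Includes a Poisson read/count simulator, SAM and
    GTF/BED interfaces, and a precision/recall evaluation protocol based on
    exact internal exon-boundary matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
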