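Package: pannumt
Title: Pan-Mitogenome Based Discovery of Nuclear Mitochondrial Segments (NUMTs)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies nuclear mitochondrial DNA segments (NUMTs) by querying
    a diversity-aware pan-mitogenome pool against a nuclear genome with
    seed-and-extend local alignment under affine-gap scoring and
    Karlin-Altschul e-value statistics. Provides pool construction from
    heterogeneous mitochondrial FASTA inputs (exact deduplication, full-length
    filtering, circular padding), BED-backed interval algebra for merging and
    comparing NUMT compilations and building exclusion sets, k-mer based
    scanning for short mitochondria-like nuclear segments with knee-point
    estimation of the minimum credible NUMT length, circular projection of
    hits onto the mitogenome for breakpoint profiling, and a simulator that
    plants divergence-controlled insertions with a truth set for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
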