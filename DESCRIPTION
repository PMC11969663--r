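Package: ripscope
Title: Simulation and Analysis of Repeat-Induced Point Mutation and
    Heterochromatin Dynamics in Fungal Crosses
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify repeat-induced point mutation (RIP) and
    DNA-methylation dynamics in haploid fungal crosses such as those of
    Neurospora crassa. The package provides a forward simulator of sexual
    crosses in which duplicated sequences acquire clustered G:C to A:T
    mutations under a genotype-dependent two-pathway intensity model
    (RID-only, DIM-2-only and synergistic components) coupled to a
    heterochromatin state machine with histone-deacetylase-dependent
    establishment; windowed detection of duplicated sequence by seeded
    pairwise alignment identity; parent-offspring mutation calling for
    haploid trios from pileup summaries with a filter cascade and a
    consensus mode for duplicated loci; RIP rate statistics including the
    Brunner-Munzel rank test; and bisulfite window methylation analysis
    with mutant-versus-wild-type change profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
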