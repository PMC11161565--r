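Package: patrace
Title: Private-Allele Tracing and Diversity Statistics for Polyploid
    Hybrid Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying introgression into polyploid hybrid
    complexes from reduced-representation (RADseq-style) SNP genotypes.
    Builds per-ancestor private-allele catalogues (including attribution
    of alleles to an extinct "ghost" ancestor observable only through a
    polyploid proxy population), traces catalogued alleles through derived
    individuals with per-individual normalization by recovered variant
    sites, computes population and per-individual diversity statistics
    (Hobs, Hexp, FIS, private-allele counts), scores mapping affinity of
    individuals to per-taxon pseudoreferences by mismatch-bounded locus
    matching, and fits contact-zone distance regressions of individual
    heterozygosity with a coverage-residual correction. A fully seeded
    synthetic-data generator emulates the data structure these analyses
    assume (ancestral diploid taxa with taxon-private alleles, derived
    tetraploids with per-individual ancestry weights, clonal apomict
    groups, a ghost ancestor, coverage-dependent missingness, and a
    geographic sexual/apomict contact line) and provides ground truth for
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    VariantAnnotation,
    Biostrings,
    S4Vectors,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
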