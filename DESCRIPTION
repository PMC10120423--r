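Package: varmat
Title: Server-Side Engine for Interactive Exploration of Variant Call Matrices
Version: 0.1.0
Authors@R:
    person("Engine", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Backend engine for browsing very large variant call matrices.
    Converts VCF files (haploid or diploid genotypes) into a chunked,
    compressed dosage store with random access by variant index or physical
    position, serves gapless variant slices for arbitrary genotype panels,
    computes ad hoc per-variant statistics (minor allele frequency,
    heterozygosity fraction, missing fraction), applies range filters over
    statistics and VCF-derived attributes, runs on-demand principal component
    analysis and Euclidean genetic-distance sample ordering on genomic
    windows or genes, searches GFF3 gene annotation with per-gene and
    per-exon variant counts, and exports standards-compliant VCF and GFF3
    subsets. A stateless JSON request handler, a command-line entry point
    with YAML configuration inference, and a deterministic synthetic
    VCF/GFF3 fixture generator round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    httpuv,
    rtracklayer,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
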