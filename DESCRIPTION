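Package: fntdcscan
Title: Genome Scanning for Functional Non-Tandem-Duplicated Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio detection of functional non-tandem-duplicated gene
    clusters (FNTDCs): groups of non-homologous genes that lie closer on a
    chromosome than expected by chance and share a Gene Ontology Biological
    Process annotation. The scanner slides a master window of a fixed number
    of GO-BP-annotated genes along each chromosome, probes a discrete set of
    sub-windows inside it, collapses tandem-duplicated genes to a single
    representative at a configurable protein-identity stringency, and tests
    each sub-window for GO-BP term over-representation with a hypergeometric
    test against the genome-wide GO-BP universe. Includes GFF3/FASTA/GO
    annotation parsing, an all-vs-all local protein aligner for tandem
    detection, per-cluster report bundles, cross-species GO set comparison,
    and a seeded synthetic-genome generator with planted clusters and tandem
    arrays for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
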