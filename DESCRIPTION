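Package: panfam
Title: Pangenome-Based Gene-Family Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes a gene family across a panel of genome assemblies
    (a pangenome) rather than a single reference. Members are identified per
    genome from annotated proteomes and from unannotated genomic regions via
    a calibrated domain-profile scan, clustered into orthologous gene groups
    (pangenes) with CD-HIT-style greedy clustering, and classified as core,
    softcore, shell or cloud by presence across genomes. Downstream stages
    type duplication mechanisms (singleton, dispersed, proximal, tandem,
    WGD/segmental) from homology hits, gene ranks and collinear blocks;
    associate copy-number variation with intact transposable elements in
    gene-flanking windows; estimate pairwise Ka, Ks and Ka/Ks with the
    Nei-Gojobori (1986) counting method; summarize pantranscriptome
    expression divergence; and assign subfamilies from a reference-anchored
    neighbor-joining phylogeny. A synthetic pangenome generator with full
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: blast+ (blastp, makeblastdb), mafft
Config/testthat/edition: 3
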