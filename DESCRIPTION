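Package: ScafEval
Title: Reference-Based Evaluation and Reference-Guided Scaffolding of De
    Novo Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating de novo assembled contigs against a
    chromosome-scale reference genome and for reference-guided
    scaffolding.  Alignment blocks between contigs and reference
    chromosomes (read from PAF or a tabular block format) are organised
    per chromosome, annotated with end categories and colinear runs, and
    summarised into per-chromosome coverage, identity and L50/L90
    reports.  Uncovered reference stretches, fragmentation hotspots
    (e.g. shattered centromeric repeat regions) and inverted segments
    are detected.  A scaffolder assigns, orders and orients contigs
    along reference chromosomes and infers inter-contig gap sizes,
    emitting scaffold FASTA and AGP.  A synthetic fragmented-genome
    simulator with full ground truth makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
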