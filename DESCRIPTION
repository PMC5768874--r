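Package: osseqtools
Title: Panel Design, Library Simulation, QC and Variant/CNA Analysis for
    In-Solution OS-Seq Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained computational toolkit for in-solution
    Oligonucleotide-Selective Sequencing (OS-Seq) targeted panels:
    primer-probe design and scoring (melting temperature, GC content,
    homopolymers, secondary structure, SNP overlap and genomic
    uniqueness), a paired-end read simulator with an FFPE cytosine
    deamination damage model and excision-only repair, probe-aware read
    QC metrics (on-target classification, duplicate marking, fold 80
    base penalty, coverage threshold fractions, insert-size statistics),
    a minimal Bayesian germline and tumor/normal variant caller with
    callset benchmarking, a read-depth copy-number caller based on
    median-normalized log2 ratios with iterative Thompson-Tau outlier
    detection, and droplet digital PCR quantification arithmetic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
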