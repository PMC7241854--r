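Package: rdcnv
Title: Read-Depth Copy-Number Genotyping, Allele Calling and Cross-Species
    Gene Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers integer copy number from per-window sequencing read depth
    in population panels. Depth is scaled to a continuous raw copy number
    against iteratively trimmed diploid control regions with GC-bias
    correction, then decoded with a hidden Markov model over integer
    copy-number states (Baum-Welch trained transitions, forward-backward
    posteriors), refined with a local population prior, and summarised as 99
    percent copy-number confidence intervals. Per-window intervals are grouped
    into copy-number alleles, windows are classified as diploid, fixed
    duplication (FD), copy-number variant (CNV) or unclassified, regions are
    merged, and protein-coding genes are profiled as partial, composite or
    complete FD/CNV genes. Includes cross-species ortholog crosstabs,
    permutation tests for conservation of non-diploidy and disease-gene
    enrichment, sample quality control, and a fully seeded synthetic-data
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
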