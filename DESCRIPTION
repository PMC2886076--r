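Package: crispratlas
Title: Comparative Analysis of CRISPR Arrays, cas Operons and Spacer
    Provenance in Enterobacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects CRISPR arrays de novo in bacterial genomes, rescues
    degenerate repeats with a consensus-guided fuzzy search, anchors arrays
    to core-gene loci via reciprocal-best-hit orthology, annotates cas
    operons (Ecoli and Ypest subtypes) and their decay into pseudogenes,
    builds a cross-genome spacer atlas with singleton and polarity
    statistics, matches spacers to proto-spacers in phage, plasmid and
    chromosomal sequences, detects self-targeting and anti-CRISPR arrays,
    and converts genome divergence into molecular-clock and neutral-dating
    time estimates.  Ships a synthetic-genome generator that plants the
    full CRISPR/cas architecture with a ground-truth ledger, so every stage
    of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    ape
Config/testthat/edition: 3
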