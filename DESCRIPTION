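Package: mtrecomb
Title: Repeat-Mediated Recombination and RNA Editing Analysis for Plant
    Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the structural and post-transcriptional
    dynamics of multichromosomal plant mitochondrial genomes. Models
    homologous recombination across repeat pairs (inversion across inverted
    repeats, excision/integration across direct repeats), enumerates the
    reachable genome configurations up to circular symmetry, and infers the
    transcriptional context (driving promoter) of genes in each
    configuration. Calls C-to-U RNA editing sites from stranded per-site
    base counts, annotates codon-level effects, compares the editomes of
    two haplotypes at homologous positions (conserved, lost, new, highly
    differential), normalises transcript coverage as TPM, detects
    intergenic transcription islands with a windowed threshold, and
    computes gender fold changes with repeat-aware unique-region masking.
    Includes seeded synthetic-data generators so the full pipeline runs
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
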