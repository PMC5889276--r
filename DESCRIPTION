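Package: phagechar
Title: Bacteriophage Genome Characterization Toolkit
Version: 0.1.0
Authors@R:
    person("Genome", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: De-novo characterization of small (20-60 kb) double-stranded DNA
    bacteriophage genomes: ORF/CDS calling under bacterial translation table 11
    with a minimum-product-mass filter, protein average molecular weight and
    theoretical isoelectric point (Bjellqvist pKa set), IUPAC-degenerate
    restriction-site screening on both strands, bipartite sigma-70 promoter
    search (-35/-10 boxes with a shared mismatch budget and a constrained
    spacer), native rho-independent terminator detection (inverted-repeat
    hairpin with a nearest-neighbor stem stability estimate and a U-tract
    score), sliding-window GC and GC-skew composition profiles with
    extreme-region calls, genome-packing statistics, GFF3 export, and a seeded
    synthetic phage-genome generator with a planted-feature ground-truth
    ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    BiocGenerics,
    rtracklayer
Config/testthat/edition: 3
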