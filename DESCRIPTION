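Package: clipscape
Title: CLIP Tag Extraction, Motif Enrichment and Intron Geometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cross-linking immunoprecipitation (CLIP)
    clone libraries from RNA binding protein studies: adapter-aware tag
    extraction from Sanger clone sequences, exact-match genome placement with
    contaminant screening, k-mer incidence versus a uniform baseline,
    genomic-feature classification of tags against gene models
    (intron/5'UTR/CDS/3'UTR), intron-length and splice-site-distance
    statistics, premature-termination-codon logic for alternative exons, and
    fold-change categorisation of two-condition differential-expression
    tables. Includes a seeded synthetic-data generator (genomes, gene models,
    planted binding sites, clone libraries, DE tables) so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, MotifDiscovery, AlternativeSplicing, Annotation
RoxygenNote: 7.3.3
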