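Package: plastotype
Title: Plastid Genome Polymorphism Scanning, Marker Genotyping and
    Haplotype Network Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising chloroplast genome (cpDNA) variation
    in plant germplasm, built around the olive tree (Olea europaea) plastome
    typing system. Scans multiple-aligned plastid genomes for substitutions,
    indels and microsatellite (SSR) length variation; models fluorescent
    fragment-analysis marker panels with allele binning, repeat-count coding
    and dye-aware multiplex design; collapses multilocus profiles into named
    haplotypes with frequency tables and discriminating-power statistics;
    builds reduced-median haplotype networks from ordered microsatellite and
    binary indel characters; and performs exact maximum-parsimony inference
    (Fitch scoring, exhaustive topology enumeration, bootstrap, strict
    consensus) on small nucleotide matrices. A coalescent-free simulator
    generates plastome-like alignments and population genotype tables with a
    known truth set for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
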