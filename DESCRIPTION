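Package: codonscape
Title: Codon Usage Landscapes of Multipartite Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map the synonymous codon usage landscape of a
    multipartite bacterial genome. Estimates the modal codon usage of gene
    sets by iterative G-test reweighting, measures distances between gene-set
    usages with bootstrap uncertainty and a pooled-shuffle null, computes
    tRNA adaptation indices (tAI and the modal m-tAI) from tRNA gene copy
    numbers and wobble pairing efficiencies, runs correspondence analysis of
    relative synonymous codon usage with supplementary projection of modal
    points, builds neighbor-joining trees from usage distances and compares
    topologies by the normalized Robinson-Foulds distance, partitions
    pan-genome ortholog tables into cores, singletons and nested ancestry
    layers, triages plasmidome contigs by identity, coverage and length, and
    ships a seeded synthetic-genome generator that emulates the ancestry
    gradient between a mobilome-like and a tRNA-optimal codon usage so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
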