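Package: mitocomp
Title: Comparative Analysis of Animal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of small circular genomes
    (arthropod-style 37-gene mitochondria): annotation arithmetic on
    circular coordinates (intergenic spacers, overlaps), nucleotide
    composition and strand skews, codon-usage bias (RSCU, effective number
    of codons, positional GC fractions, neutrality regression),
    Nei-Gojobori synonymous/nonsynonymous substitution estimation with
    Jukes-Cantor correction, an entropy-based substitution-saturation
    index, control-region tandem-repeat and stem-loop detection, signed
    circular gene-order extraction, gene-boundary classification against
    an ancestral order (plesiomorphic/derived/unique/synapomorphic),
    conserved-block detection, greedy rearrangement-event inference
    (transposition, inversion, inverse transposition, tandem
    duplication-random loss), parsimony-style ancestral gene-order
    reconstruction on a tree, and a breakpoint-distance gene-order
    phylogeny. Includes a synthetic-data generator with known ground
    truth for all analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Biostrings, ape, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
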