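Package: mitopop
Title: Mitochondrial Haplotype Diversity, Differentiation and Demography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Population-genetic analysis of same-locus mitochondrial
    (e.g. cox1) sequence alignments: haplotype collapsing and
    private/shared classification, diversity indices (haplotype diversity,
    nucleotide diversity, mean pairwise differences), Tajima's D and Fu's
    Fs neutrality tests with coalescent-simulation p-values, hierarchical
    analysis of molecular variance (AMOVA) and pairwise Phi-ST with
    permutation significance, island-model gene-flow estimates, mismatch
    distributions with sudden-expansion model fitting (SSD, Harpending's
    raggedness, parametric bootstrap), and median-joining haplotype
    networks. Includes a haploid structured-coalescent simulator so the
    whole pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
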