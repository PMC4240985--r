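Package: hybparent
Title: Homoploid Hybrid Parentage Inference from Multilocus Sequence Identity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the hybrid origin of cultivated plant
    varieties from nuclear and chloroplast sequence data. Implements
    per-locus marker informativeness statistics (variable and
    parsimony-informative site percentages, nucleotide diversity,
    base-composition chi-squared heterogeneity, a MaxChi-style
    recombination scan), desk-scale tree inference (neighbour joining,
    exact and heuristic Fitch parsimony, bootstrap support) with
    cyto-nuclear discordance measures, and multilocus identity-based
    parentage assignment: clone dereplication, strict allele matching
    against a wild-species reference panel, maternal-donor assignment
    from chloroplast haplotypes, and minimal parental-set inference by
    exact set cover. A seeded synthetic-data generator produces
    wild-species panels and homoploid hybrid cultivars with known truth
    so that every inference step can be benchmarked against simulated
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
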