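Package: mitochron
Title: Mitochondrial Haplogroup Phylogenies, Motif Classification and
    Coalescence Dating
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of human mitochondrial DNA:
    parsing and comparison of variant profiles in positional nomenclature
    against a reference mitogenome, motif-based haplogroup classification of
    complete and control-region (HVS-I) haplotypes, greedy maximum-parsimony
    construction of haplotype trees with edge-attached mutations and
    homoplasy reports, founder-age estimation with the rho statistic and its
    heuristic standard error as well as clock-constrained Poisson maximum
    likelihood, conversion of mutational distances to calendar ages through
    a purifying-selection-corrected molecular clock, HVS-I population
    frequency surveys, and a coalescent simulator with known node times for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
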