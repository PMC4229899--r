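Package: motifscan
Title: Uniparental Haplotype Motif Screening and Network-Based Dating
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating Y-chromosome STR and mtDNA HVS-I haplotype
    motifs as ancestry markers in large genetic-genealogical databases.
    Implements database filtering and nomenclature normalization for Y-STR
    and HVS-I records, matching of published 6- and 12-locus Y-STR motifs
    (Cohen and Levite Modal Haplotypes and Arabic counterparts) and four
    Ashkenazi mtDNA motifs, motif-by-group count tables with Yates-corrected
    chi-square association tests, Bayesian posterior probability of ancestry
    assignment given a motif, pedigree-calibrated mutation-rate models with a
    stepwise-mutation back-mutation correction, weighted median-joining
    haplotype networks with rho-statistic TMRCA estimation, and seeded
    synthetic-data generators (motif-planted databases and star genealogies)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
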