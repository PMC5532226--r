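Package: wrkykit
Title: Characterization of WRKY Transcription-Factor Gene Families
Version: 0.1.0
Authors@R:
    person("wrkykit", "developers", email = "wrkykit@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for characterizing plant WRKY
    transcription-factor gene families: detection of WRKY domains
    (conserved heptapeptide plus C2H2/C2HC zinc finger with spacer typing),
    group/subgroup classification, neighbour-joining phylogenies over
    pairwise alignment distances, bidirectional-best-hit orthologue and
    paralogue detection, Nei-Gojobori Ka/Ks estimation with Jukes-Cantor
    correction and molecular-clock dating of duplications (T = Ks/2*lambda),
    qRT-PCR delta-delta-Ct relative expression, FDR/log2-fold-change
    up-regulation calls, hierarchical expression clustering and Pearson
    co-expression networks with hub-gene extraction. Seeded synthetic-data
    generators emulate WRKY-like proteins, diverged paralogous CDS pairs and
    expression matrices so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
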