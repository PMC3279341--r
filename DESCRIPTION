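Package: profvar
Title: Polymorphism Profiling of Pollen Profilin Coding Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterises sequence polymorphism in small multigene protein
    families such as pollen profilins. Provides per-column Wu-Kabat
    variability indices and Shannon entropy profiles on multiple alignments,
    pairwise identity matrices with intra- and inter-group divergence
    summaries, ProtParam-style physicochemical calculators (molecular weight,
    isoelectric point, extinction coefficients, GRAVY, aliphatic and
    instability indices), a PROSITE-syntax motif scanner with a
    post-translational modification panel, neighbor-joining phylogenies with
    bootstrap support, and Games-Howell / Levene / ANOVA comparisons of
    variability distributions between species. A seeded generator of
    profilin-like coding-sequence families with known ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    seqinr
biocViews: Alignment, SequenceMatching, Phylogenetics, Genetics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
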