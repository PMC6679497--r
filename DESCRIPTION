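Package: synscreen
Title: Network Pharmacology Screening of Synergistic Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks candidate drugs for combination with a
    reference drug against a disease signaling network. Combines a
    target-network synergy score built on protein-protein interaction
    centralities (betweenness, closeness, PageRank) and network proximity,
    a functional synergy score from information-content semantic similarity
    of Gene Ontology annotations, and a chemical similarity score from
    LINGO SMILES substring profiles plus Gaussian pharmacophore-site
    overlap. Candidates are min-max normalized on the three axes and
    ranked by projection onto the diagonal of the score cube. Also
    provides the two-proportion trial statistics (Wald risk-difference
    intervals, 2x2 chi-square, sample-size calculation) used to validate
    a predicted combination, and seeded synthetic fixture generators for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
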