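Package: hxkdyn
Title: Comparative Protein Dynamics Analysis for Hexokinase Allostery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the conformational dynamics of a wild-type
    enzyme against a point mutant from molecular-dynamics ensembles stored
    as multi-model PDB files: per-residue root-mean-square fluctuations and
    their difference maps, dynamic cross-correlation matrices, residue
    interaction networks with betweenness-centrality and shortest-path
    participation analyses, radius-of-gyration statistics of domain
    opening and closing, side-chain chi1 rotamer analysis, grid-based
    cleft-volume estimates, and the accompanying non-parametric statistics
    (Kruskal-Wallis, Conover-Iman post hoc, Cohen's d). Also includes
    Michaelis-Menten kinetics estimation via Lineweaver-Burk regression
    and growth-curve doubling-time quantification, plus seeded synthetic
    generators for correlated-fluctuation and hinge open/close
    trajectories used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
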