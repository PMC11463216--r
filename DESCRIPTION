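Package: coralclone
Title: Agent-Based Clonal Growth Simulation of Scleractinian Coral Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the clonal growth of scleractinian (stony) coral colonies
    as an agent-based model on a triangular surface mesh, where every vertex is
    an individual polyp. Colonies grow by normal-gated surface accretion, clone
    by adaptive edge subdivision with Bezier surface interpolation, fuse
    over-crowded polyps by edge collapse, and ramify through a self-regulated
    branching rule with apical (leader) polyps. Five parameters (the growth-mode
    gate [smin, smax], the elongation rate, the subdivision distance, the
    inter-branching distance, and the branching angle) reproduce massive,
    cauliflower, columnar, branching, tabular and encrusting morphotypes.
    Includes morphometrics (inter-polyp distance, neighbour counts, colony
    height and radius, branch diameters), parameter sweeps, mesh export to
    OBJ/PLY/STL, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
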