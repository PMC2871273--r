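Package: cotransfold
Title: Cotranslational Fragment-Assembly Protein Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo fragment-assembly folding of protein backbones with a
    cotranslational twist: chains can be extruded and folded sequentially from
    the N-terminus (the sense of translation), from the C-terminus (reverse
    sense), or folded non-sequentially from a fully extended conformation under
    a shared cycle budget. Includes backbone construction from torsion angles
    with ideal covalent geometry, an idealized torsion-fragment library, a
    seedable Metropolis annealer, model-versus-native evaluation (GDT_TS with a
    deterministic superposition search, 11-residue window quality profiles,
    secondary-structure-aware terminus trimming, a van-der-Waals clashscore,
    and an average-logarithmic-ratio contact statistic), a three-state
    secondary structure assigner, synthetic toy-protein generators for
    desk-scale directional experiments, and packaged per-protein GDT_TS tables
    for the paired forward-versus-reverse statistical comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
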