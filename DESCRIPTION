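Package: membrins
Title: Continuum Elasticity of Shallow Protein Insertions in Stressed
    Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the elastic binding energetics of shallow hydrophobic
    protein insertions (amphipathic-helix-like rods) embedded into the outer
    monolayer of a lipid bilayer carrying intra-membrane stresses.  The
    bilayer cross-section is modelled by plane-strain linear elasticity with
    depth-dependent moduli and a trans-monolayer lateral stress profile, and
    solved with a quadratic-triangle finite element method on adaptively
    refined meshes.  Five independent protocols of stress generation
    (monolayer spontaneous curvatures, external torque, lateral stretching)
    are supported, the insertion embedding energy is decomposed into void,
    perturbation and shape-relaxation contributions, and relative binding
    constants are derived.  Includes fitting of insertion length and
    embedding depth to measured binding of ALPS motifs to liposomes of
    different sizes and lipid compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
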