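Package: xbtraj
Title: Halogen-Bond Geometry and Occupancy Analysis for Protein-Ligand
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify halogen bonds (XBs) in protein-ligand
    structures and molecular-dynamics trajectories: per-frame X...A
    distance and C-X...A sigma-hole angle, classification of the
    distance-angle plane into primary and secondary XB regions,
    occupancy and interval-median statistics, ligand RMSD after
    binding-pocket superposition, hierarchical frame clustering with
    representative-frame selection, and replicate selection by
    geometric stability. Includes an XSAR (halogen-substitution
    structure-activity) module that finds matched halogenated/parent
    ligand pairs from an activity table, computes the Xeffect potency
    ratio, and classifies chemotypes by the distance between the basic
    centre (PI) and aromatic ring centroid (AR) over a conformer
    ensemble, plus a ground-truthed synthetic trajectory generator for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
SystemRequirements: OpenBabel (obabel on the PATH) for the XSAR module
Config/testthat/edition: 3
RoxygenNote: 7.3.3
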