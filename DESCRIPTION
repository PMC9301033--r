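Package: ifpgrow
Title: Interaction-Fingerprint-Guided Scoring and Fragment Growing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for structure-based lead optimization built around
    residue-wise protein-ligand interaction fingerprints. Encodes eight
    interaction classes (hydrophobic, two aromatic stacking geometries,
    two hydrogen-bond directions, two salt-bridge directions, metal
    coordination) per protein residue into a bit vector, scores docking
    poses by negative cosine similarity to a crystallographic reference
    fingerprint (IFP_CS), and uses that score inside a deterministic
    generational fragment-growing algorithm with mutation, crossover and
    elitist selection. Also provides cross-docking benchmark analytics
    (symmetry-corrected RMSD, success rates, consensus averaging), a
    shared-feature pharmacophore model builder and pose filter, Gaussian
    shape and electrostatic similarity scoring, per-generation population
    analytics, and a synthetic toy-complex generator with planted
    interactions for fully offline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
SystemRequirements: Python (>= 3.8) with RDKit (deterministic 3D conformer
    embedding), OpenBabel (via ChemmineOB)
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
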