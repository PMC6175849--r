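Package: ccbarrel
Title: Geometric and Energetic Analysis of Higher-Order Coiled-Coil Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing alpha-helical coiled-coil assemblies above the
    classical dimer-to-tetramer range: knobs-into-holes (KIH) contact detection
    and packing-angle classification, heptad-register and interface-type
    assignment, point-group and screw symmetry detection in homomeric bundles,
    lumen (pore) radius profiling of alpha-helical barrels, all-vs-all
    sequence-threading specificity matrices with soft-steric scoring, and
    macroscopic stepwise pKa fitting of buried ionizable clusters with a
    generalised Henderson-Hasselbalch model. A deterministic Crick-parameterised
    generator builds idealized cyclic, slipped, antiparallel and collapsed
    bundles so that every analysis stage can be exercised on synthetic
    structures of known geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ccbarrel-package.R'
    'crick.R'
    'data-residues.R'
    'kih.R'
    'lumen.R'
    'pipeline.R'
    'structures.R'
    'threading.R'
    'titration.R'
    'utils-geometry.R'
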