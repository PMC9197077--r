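Package: SIFtNA
Title: Structural Interaction Fingerprints for Nucleic Acid-Ligand Complexes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies non-covalent interactions in complexes of
    nucleic acids (RNA or DNA receptors in PDB format) with ligands
    (multi-record SDF), and encodes them as Structural Interaction
    Fingerprints (SIFts) at three resolutions (SIMPLE, PBS, FULL). Nine
    interaction classes are detected under configurable geometric criteria:
    hydrogen bonds (distance-only or donor-H-acceptor angle mode), halogen
    bonds, cation-anion, Pi-cation, Pi-anion, Pi-stacking, metal
    cation-mediated (magnesium, potassium, sodium, other), water-mediated,
    and lipophilic contacts. User-defined interaction types can be added
    through a YAML plugin system based on SMARTS patterns. The package also
    provides ACUG/PuPy/Counter fingerprint wrappers, an inorganic ion
    interaction-profile mode, eight bit-vector similarity and distance
    metrics with all-vs-all matrices, interaction hot-spot statistics
    (per-atom frequencies, nucleobase face assignment, distance histograms),
    and a synthetic probe-complex generator for controlled geometries.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineOB,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralPrediction, Cheminformatics, DataImport
RoxygenNote: 7.3.3
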