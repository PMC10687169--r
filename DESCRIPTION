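Package: degronstruct
Title: Structural and Biophysical Analysis of N-Degron Recognition by UBR-Box Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how UBR-box zinc-finger domains recognise
    N-degron peptides. Reads macromolecular structures (PDB/mmCIF), generates
    crystallographic symmetry mates, detects aromatic rings and classifies
    pi-pi stacking contacts by centroid distance (R_cen) and inter-plane angle
    (gamma) into parallel, intermediate and T-shaped conformations, detects
    pi-cation contacts, types zinc coordination spheres (e.g. C2H2), measures
    hydrogen bonds and pocket waters, performs Kabsch superposition with
    sequence-based residue pairing, classifies UBR-box sequences into
    subfamilies by their Zn2-coordinating residue, and fits single-site
    isothermal titration calorimetry isotherms and thermal-shift melt curves.
    Seeded synthetic-data generators provide download-free oracles for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
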