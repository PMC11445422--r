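Package: gfpstate
Title: Chromophore-Environment Geometry and Photocycle-State Analysis for
    Green Fluorescent Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the protonation/photocycle state of
    green fluorescent protein (GFP) from crystallographic coordinates.
    Reads PDB and mmCIF structures, measures the hydrogen-bond geometry of
    the chromophore environment (His148, position 203, Ser205, Gln/Glu222,
    the bridging water of the proton relay), propagates diffraction
    precision index (DPI) coordinate errors to interatomic distances,
    classifies structures into the A, B and I states from the two
    diagnostic hydrogen-bond distances, fits pH titrations of the I-state
    fraction with the Henderson-Hasselbalch equation by weighted least
    squares, and computes reduced-density-gradient (NCI) fields from
    promolecular electron densities to characterize non-covalent
    interactions. Includes a synthetic-structure generator so the whole
    pipeline is testable without downloading deposited coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
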