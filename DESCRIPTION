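Package: coilstab
Title: Stability and Structure Analysis of Weak Coiled-Coil Heterodimers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of marginally stable coiled-coil
    heterodimers such as the kinesin-II stalk. Fits an apparent two-state
    thermal-unfolding model with linear native and unfolded baselines to
    circular-dichroism melt curves and extracts the transition midpoint,
    van't Hoff enthalpy and heat capacity change by non-linear
    Gibbs-Helmholtz stability-curve fitting, with the temperature of
    maximum stability and the free energy of unfolding at a reference
    temperature derived from the fit. Also provides mean residue molar
    ellipticity conversion and helix-content / coiled-coil indices for
    far-UV CD spectra, heptad-register annotation and charged a/d
    atypicality statistics for stalk sequences, ensemble metrics
    (superposed RMSD, per-residue RMSF, radius of gyration,
    Shrake-Rupley solvent accessible surface area, salt bridges,
    hydrophobic contacts, geometric helicity) for multi-model PDB
    conformational ensembles, and seed-deterministic synthetic-data
    generators for every input so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
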