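Package: membranekit
Title: Quantitative Analysis of Drug-Membrane Interactions from Monolayer,
    Spectroscopic, Electrochemical and Trajectory Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for studies of small-molecule interaction with
    lipid membranes. Computes elastic compression moduli and phase-transition
    pressures from Langmuir compression isotherms, pseudo-first-order
    insertion kinetics and exclusion surface pressures from constant-area
    insertion traces, transition-dipole orientations and acyl-chain tilt
    angles from polarized ATR-FTIR spectra via interface optics and band
    deconvolution, pseudocapacitance-potential curves and dielectric
    thickness changes from single-frequency impedance sweeps, and molecular
    dynamics trajectory observables (probe z-position distributions,
    hydrogen-bond time fractions, deuterium order parameters, chain tilt
    distributions, cutoff-sphere nonbonded interaction energies). Seeded
    synthetic-data generators with machine-readable ground truth make every
    stage testable without experimental raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
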