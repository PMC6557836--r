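Package: foldstab
Title: Protein Stability Analysis from Spectroscopic Denaturation and
    Trajectory Metrics
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying protein structural stability from
    spectroscopic denaturation experiments and molecular-dynamics style
    coordinate trajectories. Fits thermal, acidic and chemical (guanidine
    hydrochloride) unfolding transitions of fluorescence, circular dichroism,
    ANS and resonance light scattering curves with Boltzmann sigmoids,
    including two-step (three-state) segmental schemes, and extracts
    transition midpoints (Tm, pKa, pKb, pKc, Cm) together with
    linear-extrapolation thermodynamics (unfolding free energy and m-value)
    and half-chevron unfolding kinetics intercepts. Parses PDB structures and
    multi-model PDB trajectories and computes Kabsch-superposed RMSD, RMSF,
    radius of gyration, inter-domain distances, hydrogen-bond distances,
    occupancies and backbone hydrogen-bond counts. A synthetic-data module
    generates spectra, unfolded-fraction curves and toy trajectories with
    known ground truth so every analysis stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
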