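Package: darpkin
Title: Binding Kinetics and Structural Analysis of Affinity-Matured
    Ankyrin-Repeat Binders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying protein-protein binding from fluorescence
    and surface plasmon resonance experiments, built around the analysis of
    designed ankyrin repeat protein (DARPin) affinity maturation against
    tubulin. Implements the tight-binding (ligand-depletion) quadratic
    isotherm, mono-exponential chase and pseudo-first-order association
    kinetics, 1:1 Langmuir sensorgram fitting (per-curve and global), and
    plateau-based equilibrium analysis, together with an exact ODE oracle for
    the 1:1 scheme. Structural comparison utilities cover PDB parsing,
    Kabsch superposition and motif rotation angles, interface residues at a
    distance cutoff, steric-clash enumeration, Shrake-Rupley solvent
    accessible surface area and buried interface area, and per-region
    B-factor statistics. Additional modules rank ELISA panels into affinity
    categories and assign limited-proteolysis fragment identities from
    average masses. A synthetic-data generator produces every input type
    from explicit true parameters, noise models and seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
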