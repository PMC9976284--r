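Package: resoraman
Title: Resonance Raman Spectra from Molecular Dynamics Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale protocol for simulating UV resonance Raman spectra of
    flexible chromophores in complex environments. Trajectory snapshots are
    clustered into structural families by pairwise RMSD; harmonic normal modes
    are obtained per representative by one of four strategies (full
    diagonalization of the snapshot Hessian, partial Hessian vibrational
    analysis with a frozen environment, rotation of reference modes onto each
    frame via Kabsch superposition, or rediagonalization after projecting soft
    torsional coordinates out of the Hessian with Wilson B rows); resonance
    Raman stick intensities follow from finite-difference derivatives of the
    complex frequency-dependent polarizability along the modes, are broadened
    with a Lorentzian band shape and averaged with cluster-persistence weights.
    An analytic toy model (spectrally synthesized Hessians, Morse clusters, a
    resonance-pole polarizability) makes the whole pipeline testable without
    any electronic-structure engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
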