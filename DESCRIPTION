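Package: modewave
Title: Generalized-Mode and Wavelet Analysis of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Time-resolved vibrational analysis of molecular dynamics
    trajectories. Builds generalized vibrational modes by diagonalizing the
    time-averaged covariance of mass-weighted atomic velocities, projects
    (excited-state) trajectories onto a reference mode basis, and resolves the
    projected mode velocities in time and frequency with Morlet continuous
    wavelet spectrograms. Includes solvation and proton-transfer diagnostics
    for photoacid systems (radial distribution functions and coordination
    numbers in finite droplets, distance and dihedral time series, proton-hop
    and hydronium event detection), synthetic trajectory generators for
    validation, and a command-line interface. Trajectories are read from
    extended-XYZ files carrying positions and velocities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
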