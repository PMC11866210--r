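Package: vibmd
Title: Anharmonic Vibrational Analysis of Molecular-Dynamics Trajectories for
    Adsorbed Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts time-averaged structures, glide-symmetry statistics,
    anisotropic thermal ellipsoids, vibrational densities of states and
    local-mode peak assignments from molecular-dynamics trajectories of
    adsorbed molecules. Trajectories are read and written as extended-XYZ;
    spectra are computed from the power spectral density of mass-weighted
    velocity or, equivalently, from the velocity autocorrelation function;
    internal (local-mode) coordinates after Shimanouchi allow chemically
    labelled per-mode spectra and ranked peak assignment against reference
    (e.g. RAIRS) peak lists. A synthetic-trajectory generator (thermalized
    harmonic networks, Morse bonds, Langevin and Nose-Hoover dynamics,
    glide-symmetric adsorbate pairs) provides ground-truth fixtures for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
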