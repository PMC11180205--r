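Package: sen1kin
Title: Single-Molecule Kinetics of Sen1-Dependent Transcription Termination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and kinetic analysis of two-color single-molecule
    fluorescence trajectories of RNA polymerase II transcription termination
    by the Sen1 helicase. Provides a stochastic state-machine simulator for
    alternating-laser-excitation (ALEX) donor/acceptor traces with known
    ground truth; trace processing (FRET proximity ratio, PIFE ratio,
    threshold segmentation, dwell-time extraction, co-dissociation lag and
    polymerase fate classification); closed-form dwell-time densities
    (single exponential, photobleaching-corrected exponential,
    single-molecule Michaelis-Menten, hypoexponential two-step); and global
    histogram least-squares and maximum-likelihood fitting with held and
    shared parameters, secondary Michaelis-Menten fits, Gaussian peak fits,
    and a one- versus three-dimensional diffusion model comparison for
    post-termination polymerase sliding.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
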