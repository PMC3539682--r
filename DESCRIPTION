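Package: atrialbench
Title: Benchmarking of Human Atrial Myocyte Electrophysiology Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ionic models of the human atrial myocyte (Courtemanche,
    Nygren, Maleckar) with control and chronic atrial fibrillation
    variants, integrated with a Rush-Larsen/forward-Euler scheme;
    explicit finite-difference monodomain simulation on 1D strands and
    2D patches; protocols for action potential features, alternans,
    APD/CV/ERP/wavelength restitution, S1-S2 cross-field rotor
    initiation, phase-singularity tracking and pseudo-ECG dominant
    frequency analysis; plus synthetic fixtures (mock excitable cell,
    plane waves, vortex phase fields) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
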