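Package: dbsdti
Title: Pre- Versus Post-Operative Diffusion MRI Comparison for Deep Brain
    Stimulation, on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying how deep-brain-stimulation
    (DBS) electrode implantation degrades diffusion MRI analyses. Generates
    synthetic pre/post-operative diffusion-weighted sessions with known fiber
    geometry, susceptibility-artifact dropout and per-volume head motion;
    performs volume-to-b0 rigid motion correction with gradient reorientation;
    estimates diffusion tensors and FA/MD/RD scalar maps; computes mask-based
    SNR and CNR; classifies regions of interest as artifact-affected and runs
    a Kolmogorov-Smirnov-gated Wilcoxon/paired-t decision tree per region;
    fits a Bayesian ball-and-stick fiber model by Markov chain Monte Carlo
    (up to two fibers per voxel) and performs probabilistic streamline
    tractography with classification targets; and summarizes tract retention
    with the index of connection probability, streamline density, percent
    change and voxel-wise Welch tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
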