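Package: periseg
Title: Perioperative Brain Tumor MRI Segmentation, Reporting and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-model computational pipeline for standardized perioperative
    CNS-tumor MRI reporting: preprocessing of co-registered MR volumes,
    sliding-window assembly and ensembling of probability maps from pluggable
    patch predictors, two-step probability postprocessing, cross-structure mask
    refinement, RANO-2.0-aligned volumetric and surgical reporting, and a
    multi-level (patient-, voxel-, and object-wise) validation framework with
    Hungarian component matching. Ships a synthetic perioperative phantom
    generator so the full pipeline runs without external data or trained
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    clue,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
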