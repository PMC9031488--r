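Package: earlbench
Title: Phantom-Based Benchmarking of Harmonized PET/CT for Radiotherapy Planning
Version: 0.1.0
Authors@R:
    person("earlbench", "developers", email = "earlbench@example.org", role = c("aut", "cre"))
Description: Digital-phantom evaluation pipeline for harmonized PET/CT
    quantification in radiotherapy planning. Simulates voxelized activity
    phantoms (uniform calibration cylinder, NEMA-style six-sphere body
    phantom, anthropomorphic nested-insert set), emulates EARL1/EARL2
    reconstruction protocols by Gaussian point-spread-function blurring and
    volume-preserving downsampling, computes SUVmax/SUVmean/SUVpeak,
    recovery coefficients and EARL acceptance checks, runs two-stage
    resampling chains (PET grid to CT grid to dose grid) with nearest,
    trilinear and tricubic-spline interpolation, segments metabolic active
    tumor volumes by fractional-SUVmax thresholding with
    affinity-propagation sub-clustering, and scores segmentations by volume
    deviation and shape (Jaccard) coefficient. Includes minimal NIfTI-1
    image input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
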