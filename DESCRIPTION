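Package: ablasim
Title: Fast Axisymmetric Simulation of Microwave Liver Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates water-cooled coaxial-monopole microwave ablation of liver
    tissue and tissue-mimicking phantoms in a 2D axisymmetric geometry. Solves the
    2.45 GHz frequency-domain electromagnetic problem for the applicator, converts
    the field to a volumetric heat source, integrates Pennes' bioheat equation in
    time with blood perfusion, metabolic heat and convective needle cooling, and
    derives necrosis zones from the Arrhenius thermal-damage integral and a
    critical-temperature (60 degree Celsius) threshold. Necrosis masks are revolved
    into 3D voxel volumes and compared against segmented reference zones with Dice,
    Hausdorff and mean surface-distance metrics after rigid registration. Includes
    synthetic fixtures (ellipsoidal reference zones with optional vessel-shaped
    defects, saturating sensor temperature curves) so the whole pipeline is testable
    without external data, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    grDevices,
    stats,
    utils,
    mgcv,
    yaml,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
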