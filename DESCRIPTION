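Package: periSpace
Title: Peripersonal Space and Affordance Volumes from Insect Whole-Body Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates the peripersonal space of a walking insect from
    whole-body kinematics. Provides a standardized stick-insect body model
    with forward and inverse kinematics of the 3-DoF legs and 2-DoF
    antennae, a synthetic motion-capture trial generator (walking,
    searching, rod climbing), weighted occupancy-density estimation of
    tip, contact and action volumes on a 1 mm grid with Gaussian
    smoothing and density thresholding, pairwise affordance volumes as
    volume intersections, detection and summary statistics of first
    limb-rod contacts, and an analysis of inter-leg coordinate transfer
    that compares linear regression against single-hidden-layer neural
    networks with optional skip connections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, MASS
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
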