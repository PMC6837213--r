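Package: musteloTrab
Title: Trabecular Bone Morphometry and Phylogenetic Comparative Analysis
    of Mustelid Limb Bones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies trabecular bone architecture in cubic volumes of
    interest extracted from micro-CT stacks of long-bone epiphyses (bone
    volume fraction, trabecular thickness and separation by maximal
    inscribed spheres, connectivity density from the Euler characteristic,
    bone surface by Cauchy-Crofton stereology, and the mean-intercept-length
    fabric tensor with its degree of anisotropy), and relates those
    parameters to locomotor habits in a phylogenetic framework:
    lambda-optimised generalised least squares, residual-randomisation
    permutation AN(C)OVA with pairwise contrasts, phylogenetic principal
    components, two-block partial least squares, Fitch parsimony and Mk
    stochastic character mapping.  A synthetic-data module generates binary
    microstructure phantoms with analytic ground truth and comparative trait
    tables simulated under Brownian motion, so that every stage of the
    pipeline is testable without original scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    tiff,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    nlme,
    optparse
Config/testthat/edition: 3
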