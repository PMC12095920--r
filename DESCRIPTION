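Package: apichap
Title: Aggregation Kinetics and Coarse-Grained Simulation of Tau
    Inhibition by Chaperonin Apical Domains
Version: 0.1.0
Authors@R: person("apichap", "maintainers", email = "apichap@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse thioflavin-T aggregation time courses
    (replicate averaging, control subtraction, normalisation, fitting of a
    sigmoidal transition between two linear baselines, half-time comparison
    and half-time concentration scaling), to forward-simulate and globally
    fit moment-equation models of amyloid formation (nucleation-elongation,
    secondary nucleation, fragmentation, saturating elongation plus
    fragmentation), to run coarse-grained C-alpha Langevin dynamics of a
    folded chaperonin apical domain together with a disordered tau chain
    (native-topology contacts, Debye-Hueckel electrostatics, hydrophobicity
    -scaled attraction), and to turn the resulting trajectories into
    residue-residue interaction-probability maps and binding-segment calls.
    A synthetic-data module generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
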