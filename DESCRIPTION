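Package: fretKinetics
Title: Quantitative Analysis of Multi-State Kinetics in Diffusion-Based
    Single-Molecule FRET Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to resolve and quantify conformational exchange between
    multiple states in single-molecule FRET experiments on freely diffusing
    molecules. Provides analytic color fluorescence correlation spectroscopy
    (FCS) models for N-state kinetic networks with coexisting static
    backgrounds, time-correlated single photon counting (TCSPC) decay models,
    a joint TCSPC+FCS global fit with Markov chain Monte Carlo ambiguity
    mapping, static and dynamic FRET-lines with occupancy-time distribution
    theory, filtered-FCS species correlations, dynamic photon distribution
    analysis, and a photon-level Monte Carlo simulator of diffusion,
    state-switching and photon emission for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    minpack.lm,
    lhs,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, SingleMolecule, FluorescenceSpectroscopy, TimeCourse
RoxygenNote: 7.3.3
Collate:
    'kinetics.R'
    'fretlines.R'
    'occupancy.R'
    'fcsmodel.R'
    'tcspc.R'
    'simulator.R'
    'correlate.R'
    'ffcs.R'
    'pda.R'
    'globalfit.R'
    'io.R'
    'workflow.R'
    'fixtures.R'
    'RcppExports.R'
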