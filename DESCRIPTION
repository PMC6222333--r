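Package: MFEPath
Title: Minimum Free Energy Paths by the String Method in Collective Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the string method in collective variables for mapping
    minimum free energy pathways (MFEPs) on multi-basin energy landscapes:
    restrained overdamped-Langevin sampling with harmonic anchors, mean-force
    and metric-tensor estimation from trajectory time averages, metric-scaled
    projected steepest-descent evolution of a discretized string with
    smoothing and equal-arc-length reparametrization, free-energy integration
    along the converged path with stationary-state classification, committor
    validation of transition states, and analysis of monitored coordinates
    (dihedral conformer populations, distance series). Ships analytic
    benchmark surfaces (Mueller-Brown, double well, multi-barrier proton-relay
    chains) with exact gradients and brute-force oracle path searches, plus
    transition-state-theory rate/barrier and half-life conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    pracma,
    igraph,
    cluster
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'MFEPath-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'analysis.R'
    'cv.R'
    'sampler.R'
    'committor.R'
    'meanforce.R'
    'string.R'
    'surfaces.R'
    'io.R'
    'config.R'
    'oracle.R'
    'profile.R'
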