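Package: usdimer
Title: Dimerization Thermodynamics and Kinetics from Umbrella Sampling
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs self-association free-energy landscapes of small
    amphiphilic drugs from umbrella-sampling time series and converts them
    into experimentally comparable numbers. Implements self-consistent WHAM
    for 1D profiles, per-sample Boltzmann reweighting for 2D
    distance-orientation surfaces, the standard-state dimerization free
    energy and concentration-dependent dimer fractions, position-dependent
    diffusion coefficients from restrained trajectories, diffusion-controlled
    association rates from the steady-state Smoluchowski flux, and
    mean first-passage times for orientational flipping on a 1D landscape.
    Ships a calibrated analytic reference surface emulating amphotericin B
    dimerization together with overdamped-Langevin samplers, so the whole
    pipeline can be exercised and validated end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
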