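Package: statewalk
Title: Behavioural-State Inference for Movement Trajectories at Varying
    Temporal Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the temporal grain of animal movement
    trajectories affects Bayesian behavioural-state inference. Simulates
    two-regime correlated random walks, emulates GPS-collar observation
    (fix dropouts, 2D/3D flags, PDOP noise), screens and subsamples fix
    tables, converts positions to movement rates and turning angles, fits
    one- to three-state Weibull x wrapped-Cauchy mixture random-walk models
    by Metropolis-within-Gibbs sampling, resolves label switching with the
    Stephens relabeling algorithm, and summarises posteriors as mean density
    curves with standard-deviation bands, mean turn vectors, per-point state
    probabilities and classification accuracy against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
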