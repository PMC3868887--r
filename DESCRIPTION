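Package: flymi
Title: Mutual Information in a Stochastic Model of the Drosophila Olfactory Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates odor-to-mushroom-body information transmission in an
    abstract model of the Drosophila olfactory system: panels of odors reach
    random subsets of 50 olfactory projection neurons, projection-neuron
    activation is a probabilistic function of odor concentration, binary
    threshold Kenyon cells read the projection-neuron state through a random
    Bernoulli connectome, and activity-dependent feedback inhibition
    stochastically deletes Kenyon-cell spikes. Transmission efficiency is
    quantified as the mutual information between odor identity and the
    Kenyon-cell population state, estimated with the plug-in estimator plus
    quadratic-extrapolation correction of the finite-sampling bias. Includes
    tidy parameter-sweep drivers over connectivity rate, firing threshold,
    inhibition strength and concentration, with ggplot2 heatmaps of the
    resulting information surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
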