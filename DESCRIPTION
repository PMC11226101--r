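Package: lifevt
Title: Extreme Value Statistics of Inter-Spike Intervals from a Stochastic
    Leaky Integrate-and-Fire Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a leaky integrate-and-fire (LIF) neuron whose membrane
    time constant is redrawn from an exponential or Pareto law after every
    spike, turning the deterministic threshold-and-reset dynamics into a
    stochastic point process. Provides an extreme-value-theory (EVT) pipeline
    that extracts the per-trial maximum inter-spike interval (block maxima),
    builds sum-to-one histograms, and fits and verifies the Gumbel and
    Frechet limit laws by least squares on the histogram or by maximum
    likelihood, with coefficient-of-determination and Kolmogorov-Smirnov
    diagnostics. Includes reproducible seeded random streams, inverse-transform
    samplers, norming-constant calculators for the exponential and Pareto
    domains of attraction, an experiment orchestrator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
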