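Package: langfronts
Title: Exact Traveling Fronts in a Three-Component Reaction-Diffusion
    Model of Language Competition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a three-component reaction-diffusion model of two
    monolingual speaker communities interacting through a bilingual one.
    Provides the dimensional model and its nondimensionalization, boundary
    steady states and their symmetry classes, a tanh-expansion engine that
    reduces the system to a traveling-wave problem and derives closed-form
    front solutions together with the algebraic constraint sets and forced
    wave speeds they require, positivity-oriented parameter-selection
    algorithms for forward and backward fronts, and a method-of-lines
    solver with no-flux boundaries used to cross-validate the exact fronts
    and measure front speeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
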