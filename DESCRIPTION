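Package: bmmr
Title: Continuous-Time Two-Sex Matrix Population Models with Explicit Mating
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear, frequency-dependent stage-structured population
    models for two-sex demography in continuous time. The life cycle is
    decomposed into union formation (mating), birth, and transition rate
    matrices whose average is the projection matrix; mating is modelled
    with generalized weighted (Holder) mean mating functions. Supports
    monogamous pairs and polygynous harems of arbitrary maximum size,
    equilibrium stage structure and long-term growth rate via integration
    of the frequency dynamics on the simplex, and parameter sweeps for
    sex-biased harvest scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
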