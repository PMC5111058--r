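Package: runpause
Title: Exact Moments and Simulation of Run-and-Pause Motor Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and Monte Carlo tools for the two-state (run-and-pause)
    motility model of cytoskeletal motor proteins. Computes exact ensemble mean
    squared displacements for unidirectional motion along a single filament and
    for persistent motion on a coarse-grained two-dimensional filament network,
    the running anomalous-diffusion exponent, crossover times to the asymptotic
    ballistic or diffusive regime, asymptotic diffusion constants, and phase
    diagrams over the state-switching probabilities. Includes a brute-force
    enumeration oracle, a seeded ensemble simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
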