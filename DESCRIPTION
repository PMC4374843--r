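Package: decoyburst
Title: Stationary Protein Distributions for a Bursty Self-Regulating Gene
    with Decoy Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stationary protein copy-number distributions for a gene
    that is expressed in exponentially sized bursts, activates its own
    transcription non-cooperatively, and is titrated by decoy binding sites
    on the DNA. Binding is reduced by a quasi-steady-state approximation,
    leaving a one-dimensional piecewise-deterministic Markov process whose
    stationary density is available in closed form (with a quadrature
    fallback for degenerate parameter combinations). The package classifies
    the density as unimodal or bimodal on linear and log10 scales, traces
    the bimodality boundary curves in the (basal rate, promoter dissociation
    constant) plane, analyses the deterministic reduction and its
    bistability, and provides an exact stochastic simulator of the burst
    process for independent validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
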