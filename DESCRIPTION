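Package: heunspec
Title: Closed-Form Three-Term Recurrences, Heun Series, and Relaxation
    Spectra of Binary-Choice Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the general linear three-term recurrence relation in
    closed form through a family of recursively defined orthogonal
    polynomials, equivalent to, but more direct than, finite continued
    fractions.  The solution yields the Frobenius series coefficients of
    the general and confluent Heun equations and the accessory-parameter
    quantization polynomial whose roots give the full relaxation
    eigenspectrum of one-dimensional one-step continuous-time Markov
    chains.  Ships two worked social-choice applications (the fully
    asymmetric recruitment model of binary choice and the vacillating
    voter model) with exact stationary distributions, spectral time
    evolution, stochastic simulation oracles, and an exact big-integer
    arithmetic tier for rational recurrence families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
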