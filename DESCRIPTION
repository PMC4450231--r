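Package: ivivcr
Title: In Vitro-In Vivo Correlation Modeling with Multicompartmental Dissolution Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building in vitro-in vivo correlations (IVIVC) and
    relationships (IVIVR) for immediate-release oral formulations from
    multicompartmental dynamic dissolution data. Includes an in-silico
    four-compartment gastrointestinal transit and dissolution simulator
    (stomach, duodenum, jejunum, ileum plus a collection canister) with
    pH-dependent weak-acid solubility and buffered/nonbuffered formulation
    presets; numerical convolution and deconvolution against a
    polyexponential unit impulse response; classical level-A correlation
    fitting (linear and quadratic); a nonconventional compartmental IVIVR
    that maps a triexponential fit of a single-compartment dissolution
    curve directly onto the plasma profile through a logarithmic time
    scaling and two linear scaling constants; a hybrid differential
    evolution / particle swarm (DEPS) global optimizer used by the
    nonlinear fits; and FDA-style prediction-error validation together
    with dissolution similarity factors f1/f2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
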