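Package: pident
Title: Practical Identifiability Diagnostics for Dynamic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the practical identifiability of parameters of
    discrete-time and continuous-time dynamical models through three
    complementary diagnostics: collinearity indices of the scaled
    sensitivity matrix for arbitrary parameter subsets (local and
    prior-averaged), profile-likelihood confidence intervals together
    with a risk index derived from the supremum confidence level at
    which the interval stays finite, and the average relative error of
    repeated least-squares estimation on synthetic noisy datasets. Ships
    two worked case studies: the LNAS sugar-beet growth model (daily
    discrete step driven by temperature and radiation) and an SIR-type
    epidemic model of a plant stem population, plus generators for
    synthetic weather inputs and Gaussian-noise observation datasets.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
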