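Package: depcorr
Title: Tests for Comparing Two Dependent Correlations with Overlapping Variables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical tests for the null hypothesis that two variables
    are equally correlated with a shared third variable, i.e. comparing the
    dependent correlations r(X1,Y) and r(X2,Y) computed on one sample. Ten
    classical tests are provided (Pearson-Filon, Olkin, Hotelling, standard
    Williams, Hendrickson-Stanley-Hills, Dunn-Clark, Steiger,
    Hittner-May-Silver, Meng-Rosenthal-Rubin, and the Zou confidence-interval
    method), together with the feasibility region of trivariate correlation
    matrices, generators of correlated non-normal data (beta, lognormal and
    contaminated-normal marginals via inverse-transform and mixture
    constructions), and a Monte Carlo engine for Type I error, power and
    robustness experiments. A command-line interface exposes the tests, the
    feasibility diagnostics, the data generators and the simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
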