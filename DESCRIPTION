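Package: clonodiv
Title: Species Richness Estimation for Clonotype Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Diversity (species richness) estimation for T-cell receptor
    repertoires and other heavily skewed populations. Provides individual-based
    rarefaction (exact hypergeometric and resampling), the classical
    non-parametric richness estimators (Chao1, bias-corrected Chao1, ACE,
    Chao2, ICE, Bootstrap, Good-Turing) together with Shannon, Simpson,
    Jaccard and Morisita-Horn indices, the DivE rarefaction-curve-extrapolation
    estimator with its four model-selection criteria, an evaluation harness
    that quantifies estimator bias with sample size, and a synthetic clonotype
    population simulator including a PCR amplification-bias model that
    reproduces false saturation of read-based rarefaction curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
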