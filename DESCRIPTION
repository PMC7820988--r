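Package: selstab
Title: Stability of Regression Models After Data-Driven Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Resampling-based stability assessment for multivariable linear,
    logistic and Cox regression models obtained by backward elimination.
    Implements variable inclusion frequencies, model selection frequencies,
    relative conditional bias, root mean squared difference ratios and the
    derived shrinkage factors, estimated from bootstrap or m-out-of-n
    subsampling ensembles.  Ships a calibrated synthetic-data generator
    emulating a typical medical observational study and a simulation engine
    that approximates the estimands of the stability measures and
    benchmarks their resampling estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
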