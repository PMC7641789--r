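Package: gaitwave
Title: Gait Features and Clinical Validation from a Single Lumbar Accelerometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects gait events from the vertical acceleration of a single
    lumbar-worn triaxial accelerometer using a continuous-wavelet
    (Gaussian-derivative) method, estimates spatial gait measures with the
    inverted-pendulum model, and aggregates per-stride measures into temporal,
    spatial, asymmetry, and variability features. Ships the statistical
    validation toolkit used in clinical gait studies: ICC(2,1) agreement and
    test-retest reliability with F-based confidence bounds, Bland-Altman limits
    of agreement, Kruskal-Wallis tests with Conover-Iman post hocs and false
    discovery rate correction, and longitudinal mixed-effects modelling of
    clinician gait scores with stepwise AIC selection, Type-III Wald tests,
    leave-one-subject-out cross-validation, and marginal R-squared. Includes a
    synthetic walk and cohort simulator with ground-truth events for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    nlme
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
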