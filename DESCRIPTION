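Package: tractprev
Title: Census-Tract Chronic Disease Prevalence from Multi-System EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electronic health record (EHR) based chronic disease
    surveillance at the census-tract level. Generates synthetic multi-system
    OMOP-style EHR extracts with known ground truth; deduplicates persons
    across systems by hashed identifiers and assigns each to a reporting
    system by frequency of care; applies computable phenotypes for
    hypertension and diabetes with calendar-year lookback windows; resolves
    residence to census tracts through a zip-to-tract crosswalk with
    fractional or sampled allocation; compares EHR-derived denominators and
    prevalence against census counts and model-based small-area estimates
    (coverage ratios, relative differences, concordance bands, Bland-Altman
    agreement); and fits tract-covariate linear models of prevalence.
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
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
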