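Package: geomood
Title: Mobility Features from Smartphone Geolocation for Depression Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting depressive periods from
    passively recorded smartphone location traces. Raw, unevenly sampled and
    artifact-laden geolocation fixes are filtered, downsampled onto a
    regular grid and gap-imputed; stationary samples are segmented by
    moving-average speed thresholds and clustered into recurrent places with
    incremental K-means++; ten weekly mobility features (entropy, location
    variance, home stay, transition time, total distance, cluster count and
    Lomb-Scargle diurnal-movement power) are computed over five data
    subsets; weekly QIDS-SR16 questionnaire scores label each calendar week
    and a quadratic discriminant classifier is evaluated under
    participant-wise cross-validation with class-balanced subsampling and
    greedy wrapper feature selection. A seeded synthetic cohort generator
    with a full ground-truth ledger stands in for raw clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    lubridate,
    ggplot2,
    generics,
    withr,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
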