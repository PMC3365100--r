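Package: accelbehav
Title: Behaviour Classification from GPS Speed and Tri-Axial Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning bio-logging sensor data into behaviour and
    time-activity budgets for free-living birds. Derives posture, dynamic
    body acceleration (ODBA) and dominant power-spectrum predictors from
    short tri-axial accelerometer segments attached to GPS fixes, joins
    sensor records to visual field observations under a bounded recording
    delay, fits pruned classification trees (CART with cost-complexity
    pruning, 10-fold cross-validation and the one-standard-deviation rule),
    and applies fitted models to compute diurnal and nocturnal per-habitat
    time-activity budgets. A synthetic-study generator emulates a shorebird
    field campaign (behaviour-specific acceleration signals, Markov
    behaviour sequences, a tidal landscape) so the whole pipeline can be
    exercised and tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
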