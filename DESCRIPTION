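Package: earpheno
Title: Ear Photometry and Trial Statistics for Maize Yield-Component Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based phenotyping of dried maize ears from calibrated RGB
    photographs: supervised pixel classification in CIELAB space, ear extraction
    and axis alignment, marker-controlled watershed delineation of kernel crowns,
    and computation of 25 ear-photometry traits (yield, kernel number, kernel
    geometry, ear silhouette, fill, scatter and tip abortion). Companion trial
    statistics for multi-environment testcross experiments: growing-degree-day
    accumulation, REML mixed models with hybrid BLUPs, entry-mean and plot-mean
    broad-sense heritability, reference-trait validation, heterotic-group
    comparison with Tukey compact letters, trait PCA, and Ward clustering with
    Ball-Hall selection of the cluster number. A synthetic ear renderer and
    trial simulator provide closed-form ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    lme4,
    multcomp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    generics,
    rlang,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
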