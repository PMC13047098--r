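Package: aonrvi
Title: Agronomic Optimum Nitrogen Rates from Satellite Vegetation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-season nitrogen analysis of corn strip trials from
    multispectral satellite imagery. Computes sixteen visible and
    near-infrared vegetation indices from 4-band surface-reflectance scenes,
    cleans yield-monitor point streams, screens vegetation-index-versus-yield
    regressions, fits linear-plateau and quadratic-plateau nitrogen response
    curves with agronomic screening and AIC selection, and quantifies the
    agreement between vegetation-index-based and yield-based agronomic
    optimum nitrogen rates. Includes a synthetic field-trial generator
    (spectral-mixture scenes, plateau yield responses, yield-monitor
    artifacts) so the full pipeline can be exercised and validated without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
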