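Package: urbheat
Title: City-Level Urban Heat Exposure Projections from Multi-Model Monthly Temperature Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for assessing future urban heat exposure from
    multi-model gridded monthly mean temperature simulations. Model fields of
    differing native resolution are bilinearly regridded to a standard 0.5
    degree grid, bias-adjusted against an observed reference climatology by
    per-month additive offsets (the delta method), extracted at city
    coordinates with a nearest-land-cell rule for coastal cities, reduced to
    30-year period climatologies, combined into unweighted multi-model
    ensemble means, and summarized as changes in annual, hottest-month and
    coldest-month mean temperature stratified by region and ecoregion domain.
    A synthetic-data module emulates the gridded model and reference inputs
    with a known injected warming signal so that every stage of the pipeline
    is verifiable against closed-form truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
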