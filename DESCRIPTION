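Package: gravida
Title: Wearable Biobehavioral Trajectories Across Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models baseline-normalized trajectories of wearable sleep,
    temperature, cardiorespiratory and activity metrics across pregnancy.
    Provides a from-scratch Gaussian generalized estimating equation (GEE)
    engine with exchangeable working correlation, robust (sandwich)
    covariance, B-spline and tensor-product design construction and joint
    Wald tests; weekly aggregation and individual prepregnancy-baseline
    z-scoring; population trajectory estimation for term pregnancies with
    age/BMI moderation; a gestational-age-matched 28-day pre-loss divergence
    analysis; and a seeded synthetic-cohort generator emulating the data
    structure these analyses assume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    splines,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
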