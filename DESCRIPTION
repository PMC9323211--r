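Package: ocurel
Title: Release Kinetics, Colloid QC and Ocular Tolerability for Layer-by-Layer Particles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing ophthalmic drug delivery from layer-by-layer
    coated polymeric nanoparticles. Fits the bounded tanh ("Kink") release law
    arising from a Riccati-type multifractal release model alongside the
    classical Korsmeyer-Peppas, Higuchi, Hixson-Crowell and Weibull dissolution
    models, with small-sample AICc comparison; evaluates the closed-form complex
    Riccati release dynamics and classifies its oscillatory regimes; estimates
    the fractal dimension (fractality degree) of release curves by box counting
    and the Higuchi curve-length method; post-processes dynamic light scattering
    measurements via the Stokes-Einstein and Smoluchowski relations and screens
    formulations against size, polydispersity and refractive-index limits;
    scores hen's-egg chorioallantoic membrane (HET-CAM) irritation assays; and
    provides seeded synthetic-data generators and a reproducible end-to-end
    analysis pipeline.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
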