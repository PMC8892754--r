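Package: flyforage
Title: Traveling Behaviors and Aquatic Habitat Use Along Bird Migration Routes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how the traveling behaviors of fish-eating migratory
    birds vary with the availability of aquatic habitat along the route. Provides
    trajectory quality filtering and 30-minute resampling, stopover detection by a
    daily net-displacement rule, extraction of traveling segments, five behavior
    metrics per segment (travel speed, median flight height above ground, daily
    flight hours, photoperiod-corrected day-to-night flight ratio, straightness),
    annotation with pressure-level winds (tailwind/crosswind support), weather and
    land-cover overlap, a used-versus-available randomization test of habitat
    selection, and multimodel-averaged linear mixed-effects inference (AICc/BIC
    weights, 95% confidence set, zero-method averaging). A synthetic-data module
    generates tracks, landscapes, terrain and weather grids with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    lme4,
    MASS,
    mgcv,
    stats,
    tibble,
    utils
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
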