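Package: prioritygrid
Title: Two-Level Spatial Conservation Prioritization on Nested Grids
Version: 0.1.0
Authors@R: person("Priority", "Grid Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for systematic conservation planning on nested raster grids:
    ensemble habitat-suitability modelling from presence/pseudo-absence data,
    threshold-based binary range construction with record override and
    barrier clipping, per-cell priority indices (species richness,
    irreplaceability-based conservation value and complementarity),
    reserve gap analysis with range-scaled representation targets, and
    cross-resolution congruence statistics based on Monte-Carlo permutation
    null models. Includes a synthetic-landscape generator with known ground
    truth for end-to-end testing, plus readers/writers for ESRI ASCII grids,
    occurrence CSVs and GeoJSON reserve polygons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
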