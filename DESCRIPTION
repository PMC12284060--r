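Package: mesohab
Title: Vertical and Horizontal Extent of Mesopelagic Habitat from Gridded
    Ocean Projections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the vertical and horizontal extent of mesopelagic
    habitat from gridded coupled physical-biogeochemical ocean projections.
    The upper habitat boundary is the depth at which downwelling light falls
    to a biologically motivated threshold (0.0217 W/m2, i.e. 0.1 umol
    photons/m2/s) under a bulk chlorophyll-dependent attenuation model; the
    lower boundary is the depth at which dissolved oxygen reaches a hypoxic
    threshold (63 mmol/m3), with a bottom-depth fallback. Provides the
    surrounding analysis chain: analysis-domain masking by bathymetry,
    offshore distance and latitude; per-column derived metrics (temperature
    and light at fixed depths, depth-integrated chlorophyll, euphotic depth,
    peak buoyancy frequency); annual area-weighted series, ordinary
    least-squares trends, epoch comparisons with Welch t-tests, and
    ensemble mean/spread summaries; model-versus-observation evaluation by
    co-sampling; and a seeded synthetic-ensemble generator that emulates the
    statistical structure of downscaled climate projections for testing the
    full pipeline without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
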