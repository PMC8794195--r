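Package: wardwalk
Title: Random-Walk and Fractal-Dimension Analysis of Hospital Bed-Occupancy Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to test whether a hospital's daily in-patient census
    behaves as a Brownian random walk driven by the lag between discharges
    and admissions. Implements the Sevcik fractal-dimension estimator for
    waveforms with Monte Carlo calibration ensembles at matched series
    length, distribution-free significance testing of dimension differences
    via the Vysochanskij-Petunin inequality, a nonparametric toolbox
    (runs about the median, Hodges-Lehmann location, Theil regression with
    Spearman correlation, Jarque-Bera, two-sample Smirnov), windowed
    spectral-density classification of series as white-like or
    Brownian-like, a seeded synthetic hospital-census generator with
    artifact injection, and the cleaning rules needed for command-panel
    style daily count series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
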