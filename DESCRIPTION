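Package: sptfrap
Title: Drift Quantification, Single-Particle Tracking and FRAP Analysis for
    Immobilized-Cell Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for quantitative live-cell fluorescence microscopy of
    surface-immobilized cells and vesicles. Quantifies residual cell movement by
    FFT cross-correlation of consecutive frames, detects and links single
    fluorescent particles (discoidal averaging filter, sub-pixel centroid
    localization, greedy nearest-neighbour linking), resolves mobile and immobile
    membrane-protein populations by fitting a two-population Brownian model to the
    cumulative probability distribution of step sizes, maps protein localizations
    to the centroid of the nearest eisosome, and fits single-exponential
    fluorescence-recovery-after-photobleaching (FRAP) traces to obtain mobile
    fractions, recovery halftimes and lateral diffusion coefficients. A seeded
    synthetic-data generator produces image stacks, trajectories, localization
    fields and FRAP traces with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
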