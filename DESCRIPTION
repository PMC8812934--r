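Package: fluorotax
Title: Phytoplankton Chemotaxonomy from Multi-Wavelength Excitation
    Fluorometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates nine-group chemotaxonomic phytoplankton assemblages
    and total chlorophyll-a biomass from in situ multi-wavelength excitation
    fluorometer (MEX) casts. Builds pigment-based reference compositions by
    non-negative least-squares inversion of an HPLC marker-pigment table
    against a fixed pigment:chlorophyll ratio matrix, calibrates a robust
    zero-intercept fluorescence-to-chlorophyll conversion, decomposes
    standardized nine-channel excitation spectra over a reference database by
    bounded linear least squares and reconstructs group compositions from the
    coefficients. Includes leave-one-out and leave-area-out cross-validation,
    bootstrap sensitivity analysis, PERMANOVA and NMDS community statistics,
    a depth-profile pipeline (observation segmentation, median despiking,
    1-m binning, quartile-dispersion heterogeneity, water-column
    integration), and a synthetic-data generator so the whole workflow is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    vegan,
    yaml,
    jsonlite,
    optparse
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
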