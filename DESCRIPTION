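Package: qdflux
Title: Quantification of Quantum-Dot Tagged Nutrient Tracers in Mycorrhizal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracking fluorescent quantum-dot (QD) tagged apatite, a
    traceable rock-phosphate source, through in vitro arbuscular mycorrhizal
    networks connecting two host roots. Implements spectral unmixing of
    plate-reader emission spectra into per-color QD amounts (nonnegative least
    squares against reference spectra, calibration-curve quantification,
    detection-limit estimation), conversion of QD amounts to phosphorus budgets
    and allocation/retention ratios, raster image correlation spectroscopy
    (RICS) estimation of particle number and diffusion coefficient from
    confocal image series, time-lapse root-growth quantification by image
    binarization, and the transform-and-test statistics layer used on
    allocation ratios. A synthetic-data generator produces every input the
    pipeline consumes (emission spectra, calibration plates, Brownian-particle
    raster scans, plate-level allocation tables, growth image series) with
    known ground truth, so each stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    signal,
    minpack.lm,
    car,
    EBImage,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
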