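Package: protonfilm
Title: Radiochromic Film Dosimetry for Clinical Proton Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization pipeline for radiochromic film (EBT3/EBT4)
    dosimetry in proton beams: reading flatbed-scanner film images, net
    optical density (netOD) with propagated uncertainty, batch-specific
    rational dose-response calibration and empirical inversion,
    post-irradiation darkening kinetics with differential growth rates and
    plateau detection, characterization statistics (energy dependence,
    reproducibility, sensitivity, batch variation, noise-to-signal), and
    film-versus-chamber comparison along Bragg-peak depth and lateral
    penumbra profiles.  Includes a seeded synthetic-data generator that
    emulates scanner images, calibration series, darkening time series and
    beam profiles so the whole pipeline is testable without measured data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
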