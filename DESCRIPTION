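Package: rfsig
Title: Radio-Frequency Spectral Signatures: Blind Identification and
    Resolution Analysis of Liquid Analytes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing radio-frequency spectral signatures of
    liquid solutions measured by sweep spectroscopy. Builds per-frequency
    mean-power signatures from repeated sweeps over a fixed frequency grid,
    identifies unlabeled ("blind") scans by L1 (Manhattan) nearest-neighbour
    matching against a training library, and estimates the concentration
    resolution limit of a sensor from its rescan noise floor and the
    distance-per-ppm slope between adjacent concentrations. Includes the
    benchtop solution-preparation arithmetic (replacement volumes, solute
    masses, ideal-mixing densities) for the supported experiment designs,
    and a calibrated synthetic sweep generator whose noise floor and
    inter-solution separation are tuned to printed distance statistics so
    that the full blind-trial protocol can be replicated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'spectra.R'
    'io.R'
    'benchprep.R'
    'synth.R'
    'classify.R'
    'resolution.R'
    'fixtures.R'
    'replication.R'
    'rfsig-package.R'
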